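<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="toy_ab" name="Toy two-species model">
    <listOfCompartments>
      <compartment id="cytosol" name="cytosol"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A" name="metabolite A" compartment="cytosol"/>
      <species id="B" name="metabolite B" compartment="cytosol"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="R_AB" name="A to B" reversible="false">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
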