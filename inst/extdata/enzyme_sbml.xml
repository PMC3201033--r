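<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="enzyme_kinetics">
    <listOfSpecies>
      <species id="S" initialAmount="1"/>
      <species id="E" initialAmount="1"/>
      <species id="P" initialAmount="0"/>
      <species id="CS" initialAmount="0"/>
      <species id="CP" initialAmount="0"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="k1" value="1000"/>
      <parameter id="km1" value="2000"/>
      <parameter id="k2" value="1"/>
      <parameter id="k3" value="3000"/>
      <parameter id="km3" value="1000"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="r1" reversible="true">
        <listOfReactants>
          <speciesReference species="S"/>
          <speciesReference species="E"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="CS"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><minus/>
              <apply><times/><ci>k1</ci><ci>S</ci><ci>E</ci></apply>
              <apply><times/><ci>km1</ci><ci>CS</ci></apply>
            </apply>
          </math>
        </kineticLaw>
      </reaction>
      <reaction id="r2" reversible="false">
        <listOfReactants>
          <speciesReference species="CS"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="CP"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><times/><ci>k2</ci><ci>CS</ci></apply>
          </math>
        </kineticLaw>
      </reaction>
      <reaction id="r3" reversible="true">
        <listOfReactants>
          <speciesReference species="CP"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="P"/>
          <speciesReference species="E"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><minus/>
              <apply><times/><ci>km3</ci><ci>CP</ci></apply>
              <apply><times/><ci>k3</ci><ci>P</ci><ci>E</ci></apply>
            </apply>
          </math>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
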