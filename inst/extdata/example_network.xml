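<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="example_network" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
      <compartment id="e" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="S" name="substrate" compartment="e" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="I1" name="intermediate 1" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="I2" name="intermediate 2" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="P1" name="by-product 1" compartment="e" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="P2" name="by-product 2" compartment="e" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="B" name="biomass" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="lb_uptake" value="-10" constant="true"/>
      <parameter id="ub_inf" value="1e30" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="R1" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_inf">
        <listOfReactants><speciesReference species="S" stoichiometry="1" constant="true"/></listOfReactants>
        <listOfProducts><speciesReference species="I1" stoichiometry="1" constant="true"/></listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:and>
            <fbc:geneProductRef fbc:geneProduct="g_G1A"/>
            <fbc:geneProductRef fbc:geneProduct="g_G1B"/>
          </fbc:and>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R2" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_inf">
        <listOfReactants><speciesReference species="I1" stoichiometry="1" constant="true"/></listOfReactants>
        <listOfProducts>
          <speciesReference species="P1" stoichiometry="1" constant="true"/>
          <speciesReference species="B" stoichiometry="0.08" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="g_G2"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R3" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_inf">
        <listOfReactants><speciesReference species="S" stoichiometry="1" constant="true"/></listOfReactants>
        <listOfProducts><speciesReference species="I2" stoichiometry="1" constant="true"/></listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="g_G3"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R4" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_inf">
        <listOfReactants><speciesReference species="I1" stoichiometry="1" constant="true"/></listOfReactants>
        <listOfProducts><speciesReference species="I2" stoichiometry="1" constant="true"/></listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="g_G4"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R5" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_inf">
        <listOfReactants><speciesReference species="I2" stoichiometry="1" constant="true"/></listOfReactants>
        <listOfProducts>
          <speciesReference species="P2" stoichiometry="1" constant="true"/>
          <speciesReference species="B" stoichiometry="0.12" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:geneProductRef fbc:geneProduct="g_G5"/>
            <fbc:geneProductRef fbc:geneProduct="g_G6"/>
          </fbc:or>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="EX_S" reversible="true" fast="false" fbc:lowerFluxBound="lb_uptake" fbc:upperFluxBound="ub_inf">
        <listOfReactants><speciesReference species="S" stoichiometry="1" constant="true"/></listOfReactants>
      </reaction>
      <reaction id="EX_P1" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_inf">
        <listOfReactants><speciesReference species="P1" stoichiometry="1" constant="true"/></listOfReactants>
      </reaction>
      <reaction id="EX_P2" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_inf">
        <listOfReactants><speciesReference species="P2" stoichiometry="1" constant="true"/></listOfReactants>
      </reaction>
      <reaction id="EX_B" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_inf">
        <listOfReactants><speciesReference species="B" stoichiometry="1" constant="true"/></listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="EX_B" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="g_G1A" fbc:label="G1A"/>
      <fbc:geneProduct fbc:id="g_G1B" fbc:label="G1B"/>
      <fbc:geneProduct fbc:id="g_G2" fbc:label="G2"/>
      <fbc:geneProduct fbc:id="g_G3" fbc:label="G3"/>
      <fbc:geneProduct fbc:id="g_G4" fbc:label="G4"/>
      <fbc:geneProduct fbc:id="g_G5" fbc:label="G5"/>
      <fbc:geneProduct fbc:id="g_G6" fbc:label="G6"/>
    </fbc:listOfGeneProducts>
  </model>
</sbml>
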