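<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="TOY3" name="coupled catabolism toy model" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" name="cytosol" constant="true"/>
      <compartment id="e" name="extracellular" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A" name="substrate" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false" fbc:chemicalFormula="C6H12O6"/>
      <species id="ATP" name="energy currency" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>
      <species id="B" name="biomass precursor" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>
      <species id="P" name="product" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false" fbc:chemicalFormula="C3H6O3"/>
      <species id="W" name="waste" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false" fbc:chemicalFormula="C2H4O2"/>
      <species id="A_b" name="external substrate pool" compartment="e" boundaryCondition="true" hasOnlySubstanceUnits="false" constant="false" fbc:chemicalFormula="C6H12O6"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="zero" value="0" constant="true"/>
      <parameter id="one" value="1" constant="true"/>
      <parameter id="uptake_max" value="10" constant="true"/>
      <parameter id="maint_max" value="2000" constant="true"/>
      <parameter id="big" value="1000000" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="EX_S" name="substrate uptake" reversible="false" fast="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="uptake_max">
        <listOfReactants>
          <speciesReference species="A_b" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="CAT1" name="product-forming catabolism" reversible="false" fast="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="big">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="ATP" stoichiometry="1" constant="true"/>
          <speciesReference species="P" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_gA"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="CAT2" name="waste-forming catabolism" reversible="false" fast="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="big">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="ATP" stoichiometry="1" constant="true"/>
          <speciesReference species="W" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:geneProductRef fbc:geneProduct="G_gB"/>
            <fbc:geneProductRef fbc:geneProduct="G_gD"/>
          </fbc:or>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="ANA" name="anabolism" reversible="false" fast="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="big">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
          <speciesReference species="ATP" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_gC"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="MAINT" name="ATP maintenance" reversible="false" fast="false" fbc:lowerFluxBound="one" fbc:upperFluxBound="maint_max">
        <listOfReactants>
          <speciesReference species="ATP" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="BIO" name="biomass" reversible="false" fast="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="big">
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="EX_P" name="product export" reversible="false" fast="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="big">
        <listOfReactants>
          <speciesReference species="P" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="EX_W" name="waste export" reversible="false" fast="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="big">
        <listOfReactants>
          <speciesReference species="W" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_gA" fbc:label="gA"/>
      <fbc:geneProduct fbc:id="G_gB" fbc:label="gB"/>
      <fbc:geneProduct fbc:id="G_gC" fbc:label="gC"/>
      <fbc:geneProduct fbc:id="G_gD" fbc:label="gD"/>
    </fbc:listOfGeneProducts>
  </model>
</sbml>
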