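<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="mini" fbc:strict="true">
    <listOfCompartments>
      <compartment id="e" name="extracellular" constant="true"/>
      <compartment id="c" name="cytosol" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="M_glc_e" name="glucose" compartment="e" constant="false"
               hasOnlySubstanceUnits="false" boundaryCondition="false"/>
      <species id="M_glc_c" name="glucose" compartment="c" constant="false"
               hasOnlySubstanceUnits="false" boundaryCondition="false"/>
      <species id="M_atp_c" name="ATP" compartment="c" constant="false"
               hasOnlySubstanceUnits="false" boundaryCondition="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="glc_lb" value="-0.19" constant="true"/>
      <parameter id="zero" value="0" constant="true"/>
      <parameter id="big" value="1000" constant="true"/>
    </listOfParameters>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_HK1" fbc:label="HK1"/>
      <fbc:geneProduct fbc:id="G_PKM" fbc:label="PKM"/>
      <fbc:geneProduct fbc:id="G_PYGB" fbc:label="PYGB"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="R_EX_glc_e" name="glucose exchange" reversible="true"
                fast="false" fbc:lowerFluxBound="glc_lb"
                fbc:upperFluxBound="zero">
        <listOfReactants>
          <speciesReference species="M_glc_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="R_GLCt" name="glucose transport" reversible="false"
                fast="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="big">
        <listOfReactants>
          <speciesReference species="M_glc_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_glc_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_GLYC" name="glycolysis" reversible="false" fast="false"
                fbc:lowerFluxBound="zero" fbc:upperFluxBound="big">
        <notes>SUBSYSTEM: Glycolysis</notes>
        <listOfReactants>
          <speciesReference species="M_glc_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_atp_c" stoichiometry="2" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:and>
              <fbc:geneProductRef fbc:geneProduct="G_HK1"/>
              <fbc:geneProductRef fbc:geneProduct="G_PKM"/>
            </fbc:and>
            <fbc:geneProductRef fbc:geneProduct="G_PYGB"/>
          </fbc:or>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_ATPM" name="ATP maintenance" reversible="false"
                fast="false">
        <listOfReactants>
          <speciesReference species="M_atp_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0.1"/>
            <parameter id="UPPER_BOUND" value="1000"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
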