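<?xml version="1.0" encoding="UTF-8"?>
<document>
  <setId root="7c2e94d1-63a8-4f0b-b8a5-12d9c0e4f871"/>
  <structuredBody>
    <epcSection>
      <code code="N0000190001" displayName="Live Attenuated Bacillus Calmette-Guerin Vaccine [EPC]"/>
      <relationship name="has_PE">
        <code code="N0000190101" displayName="Actively Acquired Immunity [PE]"/>
      </relationship>
      <relationship name="has_Chemical_Structure">
        <code code="N0000190201" displayName="Vaccines, Attenuated [Chemical/Ingredient]"/>
      </relationship>
      <relationship name="has_Chemical_Structure">
        <code code="N0000190202" displayName="BCG Vaccine [Chemical/Ingredient]"/>
      </relationship>
    </epcSection>
    <epcSection>
      <code code="N0000190002" displayName="Live Attenuated Intravesical Bacillus Calmette-Guerin Vaccine [EPC]"/>
      <relationship name="has_PE">
        <code code="N0000190102" displayName="Increased Macrophage Proliferation [PE]"/>
      </relationship>
      <relationship name="has_PE">
        <code code="N0000190103" displayName="Increased Immunologically Active Molecule Activity [PE]"/>
      </relationship>
      <relationship name="has_Chemical_Structure">
        <code code="N0000190201" displayName="Vaccines, Attenuated [Chemical/Ingredient]"/>
      </relationship>
      <relationship name="has_Chemical_Structure">
        <code code="N0000190202" displayName="BCG Vaccine [Chemical/Ingredient]"/>
      </relationship>
    </epcSection>
  </structuredBody>
</document>
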