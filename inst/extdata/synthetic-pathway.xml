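<?xml version="1.0"?>
<!-- A small synthetic pathway in KGML layout (not a real KEGG pathway):
     a feedback cycle g10 -> g20 -> g30 -> g10 plus a two-gene entry and a
     bidirectional binding relation, for demonstrating the parser and the
     randomized DAG construction. -->
<pathway name="path:syn00001" title="Synthetic demo pathway">
  <entry id="1" name="syn:g10" type="gene"/>
  <entry id="2" name="syn:g20" type="gene"/>
  <entry id="3" name="syn:g30" type="gene"/>
  <entry id="4" name="syn:g40 syn:g41" type="gene"/>
  <entry id="5" name="syn:g50" type="gene"/>
  <relation entry1="1" entry2="2" type="PPrel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
  <relation entry1="2" entry2="3" type="PPrel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
  <relation entry1="3" entry2="1" type="PPrel">
    <subtype name="inhibition" value="--|"/>
  </relation>
  <relation entry1="4" entry2="5" type="GErel">
    <subtype name="expression" value="--&gt;"/>
  </relation>
  <relation entry1="2" entry2="5" type="PPrel">
    <subtype name="binding/association" value="---"/>
  </relation>
</pathway>
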