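## TASK: strategy judging
Score the strategy below for answering the question against the graph schema.
Criteria: clarity (unambiguous, atomic steps), comprehensiveness (covers
everything the question asks), schema alignment (steps map onto relationships
that exist in the schema).

Question: {{question}}

Graph schema:
{{schema}}

Strategy:
{{strategy}}

Reply with exactly three integers between 0 and 10, separated by spaces, in
this order: clarity comprehensiveness schema_alignment
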