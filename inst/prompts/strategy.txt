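## TASK: strategy generation
You are planning how to answer a question using a biomedical knowledge graph.

Graph schema:
{{schema}}

Question: {{question}}

Write strategy candidate {{index}} of {{k}}: an ordered, numbered list of
concrete steps ("1.", "2.", ...). Each knowledge-seeking step must name the
schema relationship it will query. Keep steps atomic; the final step should
produce the answer to the question.
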