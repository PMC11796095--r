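## TASK: answer synthesis
Write a short natural-language answer to the question using only the computed
results below. Do not introduce any entity that is not in the results.

Question: {{question}}

Results:
{{results}}
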