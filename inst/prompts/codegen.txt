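## TASK: code generation
Translate one strategy step into R code for a reasoning-graph node.

Question: {{question}}

Graph schema:
{{schema}}

Full strategy:
{{strategy}}

Step {{index}}: {{step}}

Variables available from previous steps: {{available}}

Rules:
- Query the knowledge graph only through knowledge_extract(cypher = "...")
  (preferred) or knowledge_extract(text = "...").
- Otherwise pure computation only; there is no file, network or system access.
- Reply in exactly this layout:
OUTPUTS: comma-separated variable names this step defines
DEPENDS: comma-separated step numbers whose variables this step reads, or "none"
```r
<the code>
```
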