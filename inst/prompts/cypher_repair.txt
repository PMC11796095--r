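## TASK: cypher repair
A Cypher query failed against the knowledge graph. Rewrite it so it runs on
this schema. Supported subset: MATCH with one or two relationships, WHERE
with = / <> / IN / AND, RETURN with optional DISTINCT and LIMIT.

Schema:
{{schema}}

Query:
{{cypher}}

Error:
{{error}}

Reply with only the corrected Cypher query on a single line.
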