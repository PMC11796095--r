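## TASK: self-debugging
A reasoning-graph node failed to execute. Analyze the error and revise the
code. Keep the same output variables.

Step: {{step}}

Code:
```r
{{code}}
```

Error:
{{error}}

Variables available to the node: {{available}}

Reply with the corrected code in a single ```r fenced block.
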