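# Prompt templates live as versioned files under inst/prompts/. Each begins
# with a distinct "## TASK:" marker so scripted-backend rules can target a
# pipeline stage unambiguously.

SYSTEM_MESSAGE <- paste(
  "You are a careful reasoning assistant working over a biomedical knowledge",
  "graph. Follow the task instructions and reply in exactly the requested format."
)

load_template <- function(name) {
  path <- system.file("prompts", paste0(name, ".txt"), package = "gotqa")
  if (!nzchar(path)) stop_config(sprintf("missing prompt template '%s'", name))
  paste(readLines(path, warn = FALSE), collapse = "\n")
}

# {{key}} substitution; keys not supplied are left intact (visible in tests).
render_template <- function(text, vars) {
  for (key in names(vars)) {
    text <- gsub(paste0("{{", key, "}}"), as.character(vars[[key]]), text, fixed = TRUE)
  }
  text
}

stage_prompt <- function(template, vars) {
  llm_prompt(SYSTEM_MESSAGE, render_template(load_template(template), vars))
}

# Extract the first fenced code block (```r ... ``` or plain ```), used by
# codegen and the self-debug loop.
extract_code_block <- function(text) {
  m <- regmatches(text, regexpr("(?s)```[rR]?[ \t]*\n(.*?)```", text, perl = TRUE))
  if (length(m) == 0L) return(NULL)
  code <- sub("```[rR]?[ \t]*\n", "", m[[1]])
  code <- sub("```$", "", code)
  code <- trimws(code, which = "right")
  if (!nzchar(trimws(code))) return(NULL)
  code
}
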