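#' Build a role-tagged prompt
#'
#' All backend traffic in the pipeline flows through [llm_complete()] with
#' prompts built here: an ordered list of messages, the first of which is
#' always the system message.
#'
#' @param system system message text.
#' @param user user message text.
#' @param history optional list of earlier `list(role=, content=)` messages
#'   inserted between system and user.
#' @return A `llm_prompt` object (list of messages).
#' @export
llm_prompt <- function(system, user, history = list()) {
  stopifnot(is_string(system), is_string(user))
  msgs <- c(
    list(list(role = "system", content = system)),
    history,
    list(list(role = "user", content = user))
  )
  structure(msgs, class = "llm_prompt")
}

prompt_text <- function(prompt) {
  paste(vapply(prompt, function(m) paste0("[", m$role, "]\n", m$content), ""),
        collapse = "\n")
}

#' Deterministic scripted backend
#'
#' A fully offline stand-in for a chat-model API, used throughout the test
#' suite and the benchmark ceiling runs. Responses are selected by an ordered
#' list of rules; the first rule whose `pattern` (a regular expression)
#' matches the rendered prompt wins. A rule's `response` is either a string
#' or a `function(prompt_text)` returning one, which lets a script compute
#' answers from the prompt (e.g. emit a ground-truth query). The same rule
#' list and call sequence always produce byte-identical completions. A call
#' no rule matches raises a `script_gap_error` — a test-authoring aid, not a
#' runtime fallback.
#'
#' @param rules list of `list(pattern = <regex>, response = <string|function>)`.
#' @param id backend identifier recorded on completions.
#' @return A `scripted_backend` object.
#' @examples
#' b <- scripted_backend(list(list(pattern = "strategy", response = "1. Look it up")))
#' llm_complete(b, llm_prompt("sys", "write a strategy"))$text
#' @export
scripted_backend <- function(rules, id = "scripted") {
  for (r in rules) {
    stopifnot(is_string(r$pattern), is_string(r$response) || is.function(r$response))
  }
  env <- new.env(parent = emptyenv())
  env$transcript <- list()
  structure(list(rules = rules, id = id, env = env), class = c("scripted_backend", "llm_backend"))
}

#' Function-handle backend adapter
#'
#' The extension point for live chat APIs: `handler(prompt, params)` must
#' return the completion text, performing whatever transport it likes. A
#' handler signalling a condition of class `backend_transport_error` (see
#' [transport_error()]) is retried up to `retries` times with exponential
#' backoff; any other error, or exhausted retries, surfaces as a
#' `backend_error`.
#'
#' @param handler `function(prompt, params)` returning completion text.
#' @param id backend identifier.
#' @param retries transport-retry bound.
#' @param backoff base backoff in seconds (doubles per retry).
#' @return An `fn_backend` object.
#' @export
fn_backend <- function(handler, id = "fn", retries = 2L, backoff = 0.5) {
  stopifnot(is.function(handler), is_count(retries))
  env <- new.env(parent = emptyenv())
  env$transcript <- list()
  structure(list(handler = handler, id = id, retries = as.integer(retries),
                 backoff = backoff, env = env),
            class = c("fn_backend", "llm_backend"))
}

#' Signal a retryable transport failure from a backend handler
#' @param message error message.
#' @export
transport_error <- function(message) {
  stop(structure(
    class = c("backend_transport_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Request a completion
#'
#' The single chokepoint for model traffic: every pipeline stage calls this,
#' every call is appended to the backend's transcript, and prompt length is
#' checked against the configured budget before any transport happens.
#'
#' @param backend a [scripted_backend()] or [fn_backend()].
#' @param prompt an [llm_prompt()].
#' @param params sampling parameters; recognized keys `temperature` (default
#'   0: pipeline stages want mode-seeking, reproducible text), `max_tokens`,
#'   and `max_prompt_chars` (default 60000).
#' @return A completion: list with `text`, `backend_id`, `usage`.
#' @export
llm_complete <- function(backend, prompt, params = list()) {
  stopifnot(inherits(backend, "llm_backend"), inherits(prompt, "llm_prompt"))
  params$temperature <- params$temperature %||% 0
  params$max_prompt_chars <- params$max_prompt_chars %||% 60000L
  txt <- prompt_text(prompt)
  if (nchar(txt) > params$max_prompt_chars) {
    stop_prompt_too_long(sprintf(
      "prompt is %d characters, budget is %d", nchar(txt), params$max_prompt_chars
    ))
  }
  started <- Sys.time()
  text <- backend_respond(backend, txt, params)
  if (!is_string(text) || !nzchar(text)) {
    stop_backend(sprintf("backend '%s' returned empty completion text", backend$id))
  }
  backend$env$transcript[[length(backend$env$transcript) + 1L]] <- list(
    prompt = txt, response = text,
    latency = as.numeric(difftime(Sys.time(), started, units = "secs"))
  )
  list(text = text, backend_id = backend$id,
       usage = list(prompt_chars = nchar(txt), completion_chars = nchar(text)))
}

backend_respond <- function(backend, txt, params) UseMethod("backend_respond")

#' @export
backend_respond.scripted_backend <- function(backend, txt, params) {
  for (r in backend$rules) {
    if (grepl(r$pattern, txt)) {
      return(if (is.function(r$response)) r$response(txt) else r$response)
    }
  }
  stop_script_gap(sprintf(
    "no scripted rule matches the prompt (first 200 chars: %s)",
    substr(txt, 1, 200)
  ))
}

#' @export
backend_respond.fn_backend <- function(backend, txt, params) {
  attempt <- 0L
  repeat {
    out <- tryCatch(
      backend$handler(txt, params),
      backend_transport_error = function(e) e
    )
    if (!inherits(out, "condition")) return(out)
    if (attempt >= backend$retries) {
      stop_backend(sprintf(
        "transport failed after %d retries: %s", backend$retries, conditionMessage(out)
      ))
    }
    Sys.sleep(backend$backoff * 2^attempt)
    attempt <- attempt + 1L
  }
}

#' Inspect a backend's call transcript
#'
#' @param backend a backend object.
#' @return List of `list(prompt, response, latency)` records, in call order.
#' @export
backend_transcript <- function(backend) {
  stopifnot(inherits(backend, "llm_backend"))
  backend$env$transcript
}

#' Write a backend transcript as JSONL
#'
#' @param backend a backend object.
#' @param path destination path; one JSON object per call.
#' @return `path`, invisibly.
#' @export
transcript_write <- function(backend, path) {
  recs <- backend_transcript(backend)
  lines <- vapply(recs, function(r) {
    as.character(to_stable_json(list(prompt = r$prompt, response = r$response)))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
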