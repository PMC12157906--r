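#' @include AllClasses.R
NULL

#' Complete a prompt with a language-model backend
#'
#' @param backend an [LLMBackend] implementation.
#' @param prompt character(1) prompt text.
#' @param ... passed to methods.
#' @return character(1) reply text.
#' @export
setGeneric("llmComplete", function(backend, prompt, ...)
  standardGeneric("llmComplete"))

#' @rdname llmComplete
setMethod("llmComplete", "ScriptedBackend", function(backend, prompt, ...) {
  hit <- match(prompt, names(backend@replies))
  if (!is.na(hit)) unname(backend@replies[hit]) else backend@default_reply
})

#' @rdname llmComplete
setMethod("llmComplete", "HeuristicBackend", function(backend, prompt, ...) {
  stop("the heuristic backend answers scoring/classification structurally; ",
       "it does not complete free-form prompts")
})

#' @rdname llmComplete
setMethod("llmComplete", "ApiBackend", function(backend, prompt, ...) {
  if (!requireNamespace("curl", quietly = TRUE))
    stop("the remote backend requires the 'curl' package")
  key <- Sys.getenv(backend@api_key_env, unset = "")
  if (!nzchar(key))
    stop("no API key found in environment variable ", backend@api_key_env)
  body <- jsonlite::toJSON(list(
    model = backend@model_name,
    temperature = backend@temperature,
    messages = list(list(role = "user", content = prompt))),
    auto_unbox = TRUE)
  h <- curl::new_handle()
  curl::handle_setheaders(h, "Content-Type" = "application/json",
                          Authorization = paste("Bearer", key))
  curl::handle_setopt(h, postfields = body)
  resp <- curl::curl_fetch_memory(backend@endpoint, handle = h)
  if (resp$status_code >= 300)
    stop("backend HTTP error ", resp$status_code)
  parsed <- jsonlite::parse_json(rawToChar(resp$content))
  parsed$choices[[1]]$message$content
})

# one retry on transport failure, then NA (caller records fallback status)
completeWithRetry <- function(backend, prompt) {
  for (attempt in 1:2) {
    reply <- tryCatch(llmComplete(backend, prompt), error = function(e) e)
    if (!inherits(reply, "error")) return(reply)
  }
  NA_character_
}
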