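#' @include AllClasses.R preprocess.R evaluation.R stats.R synthetic.R
NULL

#' Read magnitude traces from CSV
#'
#' Three dialects are supported (comma-separated, UTF-8, header required;
#' labels are case-insensitive on read and canonical lower-case on write):
#' \describe{
#'   \item{wide}{`user_id,instance_id,label,s000..s179` — one trace per
#'     row. `instance_id` may be omitted and is then generated.}
#'   \item{long}{`user_id,instance_id,t,value,label` — one sample per row,
#'     ordered by `t` within instance.}
#'   \item{triaxial}{`user_id,instance_id,t,ax,ay,az,label` — converted to
#'     magnitudes via [magnitude()].}
#' }
#'
#' @param path CSV file.
#' @param format one of `"wide"`, `"long"`, `"triaxial"`.
#' @param fs sampling frequency recorded in the result.
#' @return a [TraceSet-class].
#' @export
readTraces <- function(path, format = c("wide", "long", "triaxial"),
                       fs = 256) {
  format <- match.arg(format)
  df <- read.csv(path, check.names = FALSE)
  if (format == "wide") {
    scols <- grep("^s[0-9]+$", colnames(df), value = TRUE)
    if (!length(scols)) stop("wide CSV has no sample columns s000..")
    scols <- scols[order(as.integer(sub("^s", "", scols)))]
    bad <- which(!stats::complete.cases(df[, scols]))
    if (length(bad))
      stop("row ", bad[1], ": missing/non-numeric sample values")
    if (!"instance_id" %in% colnames(df))
      df$instance_id <- sprintf("inst%04d", seq_len(nrow(df)))
    mat <- t(as.matrix(df[, scols]))
    traceSet(mat, user_id = df$user_id, instance_id = df$instance_id,
             label = if ("label" %in% colnames(df)) df$label else NA,
             fs = fs)
  } else {
    need <- if (format == "long") c("user_id", "instance_id", "t", "value")
            else c("user_id", "instance_id", "t", "ax", "ay", "az")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
      stop(format, " CSV is missing column(s): ",
           paste(miss, collapse = ", "))
    df <- df[order(df$instance_id, df$t), , drop = FALSE]
    ids <- unique(df$instance_id)
    lens <- table(df$instance_id)
    if (length(unique(lens)) != 1L)
      stop("instances differ in sample count: ",
           paste(names(lens)[lens != lens[1]][1], collapse = ", "))
    val <- if (format == "long") df$value
           else magnitude(df$ax, df$ay, df$az)
    mat <- matrix(val, nrow = lens[1],
                  dimnames = NULL)[, match(unique(df$instance_id), ids),
                                   drop = FALSE]
    first <- df[!duplicated(df$instance_id), , drop = FALSE]
    traceSet(mat, user_id = first$user_id, instance_id = first$instance_id,
             label = if ("label" %in% colnames(df)) first$label else NA,
             fs = fs)
  }
}

#' Write magnitude traces as wide CSV
#'
#' @param traces a [TraceSet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTraces <- function(traces, path) {
  stopifnot(is(traces, "TraceSet"))
  m <- assay(traces, "magnitude")
  cd <- as.data.frame(colData(traces))
  wide <- data.frame(user_id = cd$user_id, instance_id = cd$instance_id,
                     label = cd$label, t(m), check.names = FALSE,
                     row.names = NULL)
  colnames(wide)[-(1:3)] <- sprintf("s%03d", seq_len(nrow(m)) - 1L)
  write.csv(wide, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a FeatureSet as CSV with a sidecar JSON
#'
#' The CSV has columns `user_id,instance_id,label,f00..f29`; a sidecar
#' `<path>.json` documents the feature order, filter specification and
#' low-frequency band edge. Values round-trip losslessly (full double
#' precision).
#'
#' @param features a [FeatureSet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatures <- function(features, path) {
  stopifnot(is(features, "FeatureSet"))
  m <- assay(features, "features")
  cd <- as.data.frame(colData(features))
  df <- data.frame(user_id = cd$user_id, instance_id = cd$instance_id,
                   label = cd$label, t(m), check.names = FALSE,
                   row.names = NULL)
  colnames(df)[-(1:3)] <- sprintf("f%02d", seq_len(nrow(m)) - 1L)
  fmt <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  df[-(1:3)] <- lapply(df[-(1:3)], fmt)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  flt <- metadata(features)$filter
  write_json(list(feature_order = rownames(m),
                  filter = list(cutoff_hz = flt@cutoff_hz,
                                order = flt@order, fs = flt@fs),
                  low_band_hz = metadata(features)$low_band_hz),
             paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param path CSV path written by [writeFeatures()].
#' @rdname writeFeatures
#' @export
readFeatures <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  fcols <- grep("^f[0-9]+$", colnames(df), value = TRUE)
  fcols <- fcols[order(as.integer(sub("^f", "", fcols)))]
  if (length(fcols) %% 10L != 0L)
    stop("feature CSV must have a multiple of 10 feature columns")
  side <- paste0(path, ".json")
  flt <- filterSpec()
  low_band <- 10
  if (file.exists(side)) {
    meta <- read_json(side, simplifyVector = TRUE)
    flt <- filterSpec(meta$filter$cutoff_hz, meta$filter$order,
                      meta$filter$fs)
    low_band <- meta$low_band_hz
  }
  cd <- DataFrame(user_id = as.character(df$user_id),
                  instance_id = as.character(df$instance_id),
                  label = canonicalLabel(df$label))
  featureSetFromMatrix(t(as.matrix(df[, fcols])), cd, filter = flt,
                       low_band_hz = low_band)
}

#' Pipeline run configuration
#'
#' Validated bag of every tunable the end-to-end pipeline uses; unknown
#' keys are rejected. Serialized into the run manifest for provenance.
#'
#' @param preset `"paramA"` or `"paramB"` (or set `distance_k` / `top_k`
#'   explicitly).
#' @param distance_k,top_k explicit selection sizes (override `preset`).
#' @param backend `"heuristic"`, `"scripted"` or `"api"`.
#' @param model,temperature backend parameters.
#' @param dk_enabled include domain knowledge in scoring prompts.
#' @param low_band_hz,cutoff_hz,filter_order,fs preprocessing parameters.
#' @param methods methods for [evaluateAll()].
#' @param seed master seed.
#' @return a validated named list of class `"hedlm_config"`.
#' @export
runConfig <- function(preset = "paramA", distance_k = NULL, top_k = NULL,
                      backend = "heuristic", model = "heuristic",
                      temperature = 0.3, dk_enabled = TRUE, low_band_hz = 10,
                      cutoff_hz = 30, filter_order = 4L, fs = 256,
                      methods = c("ml", "random", "distance",
                                  "hedlm_paramA"),
                      seed = 42L) {
  cfg <- list(preset = preset, distance_k = distance_k, top_k = top_k,
              backend = match.arg(backend,
                                  c("heuristic", "scripted", "api")),
              model = model, temperature = temperature,
              dk_enabled = isTRUE(dk_enabled), low_band_hz = low_band_hz,
              cutoff_hz = cutoff_hz, filter_order = as.integer(filter_order),
              fs = fs, methods = methods, seed = as.integer(seed))
  if (is.null(cfg$distance_k)) {
    sel <- selectionPreset(cfg$preset)
    cfg$distance_k <- sel@distance_k
    cfg$top_k <- sel@top_k
  }
  validObject(selectionConfig(cfg$distance_k, cfg$top_k))
  validObject(filterSpec(cfg$cutoff_hz, cfg$filter_order, cfg$fs))
  structure(cfg, class = "hedlm_config")
}

#' @param path YAML file of configuration keys (unknown keys rejected).
#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  raw <- read_yaml(path)
  known <- names(formals(runConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(runConfig, raw)
}

configBackend <- function(cfg) {
  switch(cfg$backend,
         heuristic = heuristicBackend(model_name = cfg$model),
         scripted = scriptedBackend(model_name = cfg$model,
                                    temperature = cfg$temperature),
         api = apiBackend(model_name = cfg$model,
                          temperature = cfg$temperature))
}

#' Run the end-to-end pipeline
#'
#' Load (or featurize) the data, evaluate the configured methods per user,
#' and write the results: a users x methods macro-F1 CSV, a statistics
#' JSON (when at least two methods ran), and a run manifest recording the
#' full configuration and a content hash.
#'
#' @param cfg from [runConfig()] / [readRunConfig()].
#' @param input a [TraceSet-class], [FeatureSet-class], or path to a wide
#'   trace CSV.
#' @param out_dir output directory (created if needed).
#' @return the [MethodScoreTable-class], invisibly; side-effect files
#'   `scores.csv`, `stats.json`, `manifest.json` under `out_dir`.
#' @export
runPipeline <- function(cfg, input, out_dir) {
  stopifnot(inherits(cfg, "hedlm_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  features <- if (is(input, "FeatureSet")) input
  else {
    traces <- if (is(input, "TraceSet")) input
              else readTraces(input, fs = cfg$fs)
    featurize(traces,
              spec = filterSpec(cfg$cutoff_hz, cfg$filter_order, cfg$fs),
              low_band_hz = cfg$low_band_hz)
  }
  table <- evaluateAll(features, methods = cfg$methods,
                       backend = configBackend(cfg),
                       dk = defaultDomainKnowledge(cfg$dk_enabled),
                       seed = cfg$seed)
  writeScoreTable(table, file.path(out_dir, "scores.csv"))
  if (ncol(scoreMatrix(table)) >= 2L) {
    cmp <- compareMethods(table)
    write_json(list(summary = cmp$summary,
                    friedman = cmp$friedman[c("statistic", "p", "df")],
                    nemenyi = as.data.frame(cmp$nemenyi),
                    pairwise = cmp$pairwise),
               file.path(out_dir, "stats.json"), auto_unbox = TRUE,
               digits = NA)
  }
  cfg_json <- toJSON(unclass(cfg), auto_unbox = TRUE)
  write_json(list(config = unclass(cfg),
                  config_hash = sprintf("%08x",
                    sum(utf8ToInt(cfg_json) * seq_len(nchar(cfg_json))) %%
                      4294967291),
                  n_instances = ncol(features),
                  n_users = length(unique(colData(features)$user_id)),
                  timestamp = format(Sys.time(), tz = "UTC")),
             file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(table)
}
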