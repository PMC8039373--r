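#' Read a paired response / response-time dataset from CSV
#'
#' Reads two aligned rectangular CSVs (responses and times in seconds) and
#' a Q-matrix CSV into a [joint_data()]. Both data files carry a header
#' row of item labels and a first column of person labels; empty cells are
#' missing. Row and column labels of the two files must agree exactly,
#' and item labels must match the Q-matrix; mismatches are hard errors.
#' Times that are zero or negative are coerced to missing (their count is
#' reported by the returned object and a message).
#'
#' @param responses_path CSV of 0/1 responses.
#' @param times_path CSV of response times in seconds.
#' @param q_path Q-matrix CSV, as read by [read_qmatrix()].
#' @return A [joint_data()].
#' @export
read_joint_dataset <- function(responses_path, times_path, q_path) {
  for (p in c(responses_path, times_path, q_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  rd <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(df[[1]])
    m
  }
  Y <- rd(responses_path)
  tt <- rd(times_path)
  if (!identical(dim(Y), dim(tt)) ||
    !identical(rownames(Y), rownames(tt)) ||
    !identical(colnames(Y), colnames(tt))) {
    stop("responses and times files do not align (labels or shape differ)")
  }
  q <- read_qmatrix(q_path)
  if (!identical(colnames(Y), rownames(q))) {
    stop("item labels of the dataset do not match the Q-matrix")
  }
  out <- joint_data(Y, tt, q)
  if (out$n_coerced_times > 0) {
    message(out$n_coerced_times, " non-positive time(s) coerced to missing")
  }
  out
}

#' Write a dataset as aligned CSV files
#'
#' Inverse of [read_joint_dataset()]: writes the response matrix, the time
#' matrix (seconds; missing cells empty) and the Q-matrix.
#'
#' @param data a [joint_data()].
#' @param responses_path,times_path,q_path output paths.
#' @return The three paths, invisibly.
#' @export
write_joint_dataset <- function(data, responses_path, times_path, q_path) {
  stopifnot(inherits(data, "joint_data"))
  wr <- function(m, path) {
    df <- data.frame(person = rownames(m), m, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
    path
  }
  Y <- data$Y
  tt <- exp(data$logT)
  if (is.null(rownames(Y))) {
    rownames(Y) <- rownames(tt) <- paste0("P", seq_len(nrow(Y)))
  }
  rownames(tt) <- rownames(Y)
  colnames(Y) <- colnames(tt) <- rownames(data$q)
  wr(Y, responses_path)
  wr(tt, times_path)
  write_qmatrix(data$q, q_path)
  invisible(c(responses_path, times_path, q_path))
}

CHAINS_SCHEMA_VERSION <- 1L

#' Serialize / restore fitted chains
#'
#' Lossless round-trip of an `mmj_fit` (all draws, configuration, priors,
#' seeds and data) through a single self-describing file. A schema version
#' is embedded; reading a file with a different schema, or a file that is
#' not a serialized fit, is an explicit error rather than a silent partial
#' read.
#'
#' @param fit an `mmj_fit`.
#' @param path file path (conventionally `.rds`).
#' @return `write_chains()` returns `path` invisibly; `read_chains()`
#'   returns the restored `mmj_fit`.
#' @export
write_chains <- function(fit, path) {
  stopifnot(inherits(fit, "mmj_fit"))
  saveRDS(list(
    schema = "mmjoint_chains", version = CHAINS_SCHEMA_VERSION, fit = fit
  ), path)
  invisible(path)
}

#' @rdname write_chains
#' @export
read_chains <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read chains file ", path, ": ", conditionMessage(e))
  })
  if (!is.list(obj) || !identical(obj$schema, "mmjoint_chains")) {
    stop("not a serialized chains file: ", path)
  }
  if (!identical(obj$version, CHAINS_SCHEMA_VERSION)) {
    stop(
      "chains schema version ", obj$version, " not supported (expected ",
      CHAINS_SCHEMA_VERSION, ")"
    )
  }
  obj$fit
}

#' Write a run manifest
#'
#' Records what produced an output: the command, seed, configuration echo
#' and package version, as JSON next to the results, so any table is
#' regenerable from its manifest alone.
#'
#' @param path output JSON path.
#' @param command character tag of the command run.
#' @param seed integer seed used.
#' @param config a list echoing the configuration.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, seed, config = list()) {
  jsonlite::write_json(
    list(
      command = command, seed = seed, config = config,
      package_version = as.character(utils::packageVersion("mmjoint")),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
    ),
    path,
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(path)
}
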