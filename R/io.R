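# Plain-text IO: 0/1 CSV response matrices and YAML configuration for
# generating models and study grids.

# YAML 1.1 reads bare y/Y/n/N as booleans, which would swallow the N and n
# keys of the study grid; keep those as strings and restore real booleans
read_yaml_kv <- function(path) {
  keep <- c("y", "Y", "n", "N")
  h <- list(
    "bool#yes" = function(x) if (x %in% keep) x else TRUE,
    "bool#no" = function(x) if (x %in% keep) x else FALSE
  )
  yaml::yaml.load_file(path, handlers = h)
}

#' Read a 0/1 response matrix from CSV
#'
#' Accepts an optional header row of item labels and an optional first
#' column of person labels (both auto-detected: a header is assumed when
#' the first row contains non-numeric fields, a label column when the
#' first field of a data row is not 0/1).  Any other non-binary cell is a
#' parse error naming its location.
#'
#' @param path CSV file path.
#' @return An integer 0/1 matrix with person/item labels and the raw-score
#'   distribution in `attr(, "score_table")`.
#' @export
read_response_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty response matrix file: ", path)
  fields <- strsplit(lines, ",", fixed = TRUE)
  fields <- lapply(fields, trimws)
  ncol1 <- length(fields[[1L]])
  if (any(lengths(fields) != ncol1))
    stop("ragged rows in ", path, ": row(s) ",
         paste(which(lengths(fields) != ncol1), collapse = ", "))
  is_binary <- function(v) v %in% c("0", "1")
  is_numeric_tok <- function(v) !is.na(suppressWarnings(as.numeric(v)))
  # a header is assumed when the first row contains a non-numeric field
  header <- any(!is_numeric_tok(fields[[1L]]))
  body <- if (header) fields[-1L] else fields
  if (!length(body)) stop("no data rows in ", path)
  # a person-label column is assumed when data rows start with a
  # non-numeric field (numeric non-binary cells stay parse errors)
  first_fields <- vapply(body, `[`, "", 1L)
  labels_col <- any(!is_numeric_tok(first_fields))
  person_labels <- if (labels_col) first_fields else NULL
  cells <- lapply(body, function(v) if (labels_col) v[-1L] else v)
  ncol_data <- length(cells[[1L]])
  item_labels <- if (header) {
    if (length(fields[[1L]]) == ncol_data + labels_col)
      utils::tail(fields[[1L]], ncol_data)
    else stop("header length does not match data columns in ", path)
  } else NULL
  for (i in seq_along(cells)) {
    bad <- which(!is_binary(cells[[i]]))
    if (length(bad))
      stop(sprintf(
        "non-binary cell '%s' at data row %d, column %d of %s",
        cells[[i]][bad[1L]], i, bad[1L], path))
  }
  X <- matrix(as.integer(unlist(cells)), nrow = length(cells),
              ncol = ncol_data, byrow = TRUE)
  rownames(X) <- if (!is.null(person_labels)) person_labels
                 else paste0("P", seq_len(nrow(X)))
  colnames(X) <- if (!is.null(item_labels)) item_labels
                 else paste0("I", seq_len(ncol(X)))
  X <- as_response_matrix(X)
  attr(X, "score_table") <- table(rowSums(X))
  X
}

#' Write a 0/1 response matrix to CSV
#'
#' Writes a header row of item labels and a first column of person labels,
#' the format [read_response_matrix()] reads back unchanged.
#'
#' @param X 0/1 response matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_response_matrix <- function(X, path) {
  X <- as_response_matrix(X)
  df <- data.frame(person = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a generating-model specification (YAML)
#'
#' Flat key-value serialization of a [sim_spec()]: a `family` tag plus the
#' family parameters.
#'
#' @param path YAML file path.
#' @return For `read_sim_spec`, a [sim_spec()] object.
#' @export
read_sim_spec <- function(path) {
  kv <- read_yaml_kv(path)
  if (is.null(kv$family)) stop("config lacks a 'family' tag: ", path)
  family <- kv$family
  kv$family <- NULL
  do.call(sim_spec, c(list(family = family), kv))
}

#' @rdname read_sim_spec
#' @param spec a [sim_spec()] object (write only).
#' @export
write_sim_spec <- function(spec, path) {
  stopifnot(inherits(spec, "sim_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' Read a study-grid configuration (YAML)
#'
#' The config holds optional top-level `alphas` and `tests`, and a
#' `conditions` list; each condition gives `family`, `N`, `n`, `reps`,
#' `seed`, optional `B` and family parameters.
#'
#' @param path YAML file path.
#' @return A list with `conditions` (list of [sim_condition()]) and
#'   `tests` (character vector).
#' @export
read_study_config <- function(path) {
  cfg <- read_yaml_kv(path)
  if (is.null(cfg$conditions)) stop("config lacks a 'conditions' list: ", path)
  alphas <- if (is.null(cfg$alphas)) c(0.05, 0.01) else as.numeric(cfg$alphas)
  tests <- if (is.null(cfg$tests)) c("LR", "T10", "T11", "M2")
           else as.character(cfg$tests)
  conditions <- lapply(cfg$conditions, function(cc) {
    need <- c("family", "N", "n", "reps", "seed")
    if (!all(need %in% names(cc)))
      stop("condition lacks field(s): ",
           paste(setdiff(need, names(cc)), collapse = ", "))
    B <- if (is.null(cc$B)) 300L else as.integer(cc$B)
    pars <- cc[setdiff(names(cc), c(need, "B"))]
    spec <- do.call(sim_spec, c(list(family = cc$family), pars))
    sim_condition(spec, N = cc$N, n = cc$n, reps = cc$reps,
                  seed = cc$seed, alpha = alphas, B = B)
  })
  list(conditions = conditions, tests = tests)
}
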