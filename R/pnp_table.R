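#' Block-structured descriptor table for polymeric nanoparticles
#'
#' A `pnp_table` holds one row per polymeric nanoparticle (PNP): an
#' identifier, descriptor values tagged by block (`core`, `coating`,
#' `corona`), the measured zeta potential endpoint in millivolts, and a
#' train/validation split label.  Corona descriptors are binary
#' protein-fingerprint bits (1 = the protein was detected in the corona),
#' coating descriptors are small non-negative counts (for example the number
#' of sp2 carbons in the functional group), and core descriptors are
#' continuous physicochemical quantities such as the average molecular
#' weight of the polymer.
#'
#' @param descriptors numeric matrix or data frame, one column per
#'   descriptor.  Column order must match `schema$name`.
#' @param zeta numeric endpoint vector, zeta potential in mV.
#' @param schema data frame with columns `name`, `block`
#'   (`"core"`, `"coating"` or `"corona"`) and `kind`
#'   (`"continuous"`, `"count"` or `"binary"`).
#' @param ids character sample identifiers; defaults to `"1"`, `"2"`, ...
#' @param split character vector of `"T"` (training), `"V"` (validation) or
#'   `"unassigned"`; defaults to all `"unassigned"`.
#' @param core,coating optional character vectors naming the polymer core
#'   and surface coating of each sample.
#' @param reference_pred optional numeric vector of reference predictions
#'   distributed with a dataset.  Kept as metadata only; never used in
#'   fitting.
#'
#' @return an object of class `pnp_table`.
#' @seealso [pnp20()], [read_pnp_table()], [split_every_third()]
#' @export
#' @examples
#' sch <- data.frame(name = c("d1", "b1"),
#'                   block = c("core", "corona"),
#'                   kind = c("continuous", "binary"))
#' tab <- pnp_table(cbind(d1 = rnorm(6), b1 = rbinom(6, 1, 0.4)),
#'                  zeta = rnorm(6, sd = 20), schema = sch)
#' tab
pnp_table <- function(descriptors, zeta, schema, ids = NULL, split = NULL,
                      core = NULL, coating = NULL, reference_pred = NULL) {
  X <- as.matrix(descriptors)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (is.null(split)) split <- rep("unassigned", n)
  if (!is.null(colnames(X)) && !identical(colnames(X), schema$name) &&
      all(schema$name %in% colnames(X))) {
    X <- X[, schema$name, drop = FALSE]
  }
  colnames(X) <- schema$name
  x <- structure(list(
    ids = as.character(ids),
    X = X,
    zeta = as.numeric(zeta),
    split = as.character(split),
    schema = as.data.frame(schema)[, c("name", "block", "kind")],
    core = core,
    coating = coating,
    reference_pred = reference_pred
  ), class = "pnp_table")
  validate_pnp_table(x)
}

#' Validate a pnp_table against its schema invariants
#'
#' Checks that identifiers are unique, descriptor values are numeric and
#' finite where required, binary columns contain only 0/1, count columns
#' contain non-negative integers, and the endpoint is finite.  Violations
#' are reported with row (structure id) and column coordinates.
#'
#' @param x a [pnp_table()].
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_pnp_table <- function(x) {
  stopifnot(inherits(x, "pnp_table"))
  n <- length(x$ids)
  if (nrow(x$X) != n || length(x$zeta) != n || length(x$split) != n)
    stop("inconsistent row counts across table fields")
  if (anyDuplicated(x$ids))
    stop("duplicate structure_id: ",
         paste(unique(x$ids[duplicated(x$ids)]), collapse = ", "))
  if (anyDuplicated(x$schema$name))
    stop("duplicate descriptor name in schema")
  if (ncol(x$X) != nrow(x$schema))
    stop("descriptor matrix has ", ncol(x$X), " columns but schema lists ",
         nrow(x$schema))
  bad_block <- setdiff(x$schema$block, c("core", "coating", "corona"))
  if (length(bad_block)) stop("unknown block: ", bad_block[1])
  bad_kind <- setdiff(x$schema$kind, c("continuous", "count", "binary"))
  if (length(bad_kind)) stop("unknown kind: ", bad_kind[1])
  if (!all(x$split %in% c("T", "V", "unassigned")))
    stop("split labels must be 'T', 'V' or 'unassigned'")
  if (any(!is.finite(x$zeta)))
    stop("non-finite endpoint for structure_id ",
         x$ids[which(!is.finite(x$zeta))[1]])
  for (j in seq_len(ncol(x$X))) {
    v <- x$X[, j]
    nm <- x$schema$name[j]
    if (any(!is.finite(v)))
      stop("non-numeric descriptor cell at row '",
           x$ids[which(!is.finite(v))[1]], "', column '", nm, "'")
    kind <- x$schema$kind[j]
    if (kind == "binary" && any(!(v %in% c(0, 1))))
      stop("binary column '", nm, "' has value ",
           v[which(!(v %in% c(0, 1)))[1]], " at row '",
           x$ids[which(!(v %in% c(0, 1)))[1]], "' (must be 0 or 1)")
    if (kind == "count" && any(v < 0 | v != round(v)))
      stop("count column '", nm, "' has non-count value at row '",
           x$ids[which(v < 0 | v != round(v))[1]], "'")
  }
  invisible(x)
}

#' @export
print.pnp_table <- function(x, ...) {
  blk <- table(factor(x$schema$block, c("core", "coating", "corona")))
  cat("pnp_table: ", length(x$ids), " samples, ", nrow(x$schema),
      " descriptors (core ", blk[["core"]], ", coating ", blk[["coating"]],
      ", corona ", blk[["corona"]], ")\n", sep = "")
  cat("split: ", sum(x$split == "T"), " T / ", sum(x$split == "V"),
      " V / ", sum(x$split == "unassigned"), " unassigned\n", sep = "")
  cat("zeta potential range: [", min(x$zeta), ", ", max(x$zeta),
      "] mV\n", sep = "")
  invisible(x)
}

#' @export
dim.pnp_table <- function(x) c(length(x$ids), nrow(x$schema))

#' @export
as.data.frame.pnp_table <- function(x, ...) {
  d <- data.frame(structure_id = x$ids, stringsAsFactors = FALSE)
  if (!is.null(x$core)) d$core <- x$core
  if (!is.null(x$coating)) d$coating <- x$coating
  d <- cbind(d, as.data.frame(x$X, check.names = FALSE))
  d$zeta_mV <- x$zeta
  if (!is.null(x$reference_pred)) d$zeta_ref_pred_mV <- x$reference_pred
  d$split <- x$split
  rownames(d) <- NULL
  d
}

#' Restrict a table to a subset of descriptor columns
#'
#' @param x a [pnp_table()].
#' @param names descriptor names to keep (order preserved as given).
#' @return a `pnp_table` with the reduced descriptor matrix and schema.
#' @export
subset_descriptors <- function(x, names) {
  stopifnot(inherits(x, "pnp_table"))
  missing <- setdiff(names, x$schema$name)
  if (length(missing))
    stop("unknown descriptor(s): ", paste(missing, collapse = ", "))
  idx <- match(names, x$schema$name)
  x$X <- x$X[, idx, drop = FALSE]
  x$schema <- x$schema[idx, , drop = FALSE]
  rownames(x$schema) <- NULL
  validate_pnp_table(x)
  x
}

#' The packaged 20-nanoparticle benchmark dataset
#'
#' Loads the published modeling set of 20 polymeric nanoparticles with the
#' five descriptors retained by GA-PLS selection: the core average molecular
#' weight (`AMW-P`), the number of sp2-hybridized carbons in the coating
#' (`nCsp2-C`), and three binary protein-corona fingerprint bits
#' (complement C1r subcomponent `CC1rs`, apolipoprotein A-I `ApoA-I`, and
#' `kininogen-1`).  The endpoint is the observed zeta potential in mV; the
#' published train/validation labels (14 T / 6 V) and the reference
#' predicted column are carried as printed.  The reference predictions are
#' metadata only and are never used for fitting.
#'
#' @return a [pnp_table()] with 20 samples and 5 descriptors.
#' @export
#' @examples
#' tab <- pnp20()
#' table(tab$split)
pnp20 <- function() {
  read_pnp_table(
    system.file("extdata", "pnp20.csv", package = "nanoqspr"),
    system.file("extdata", "pnp20_schema.json", package = "nanoqspr")
  )
}

read_schema <- function(schema) {
  if (is.character(schema) && length(schema) == 1) {
    schema <- jsonlite::read_json(schema, simplifyVector = TRUE)
  }
  stopifnot(is.list(schema), !is.null(schema$endpoint),
            !is.null(schema$columns))
  schema$columns <- as.data.frame(schema$columns)
  schema
}

#' Read / write a descriptor table as CSV plus a schema file
#'
#' The CSV is an RFC-4180 comma-separated file with a header row and "."
#' decimal separator.  The schema (a JSON file or an equivalent list) names
#' the id, endpoint, split and optional metadata columns and tags every
#' descriptor column with its block and kind.  `write_pnp_table()` followed
#' by `read_pnp_table()` reproduces the table exactly, with values compared
#' as decimal text.
#'
#' @param path CSV file path.
#' @param schema path to a JSON schema file, or a list with elements
#'   `id`, `endpoint`, `split`, `columns` (data frame `name`/`block`/`kind`)
#'   and optional `core_name`, `coating_name`, `reference_pred`.
#' @return `read_pnp_table()` returns a [pnp_table()];
#'   `write_pnp_table()` returns `path` invisibly.
#' @export
read_pnp_table <- function(path, schema) {
  schema <- read_schema(schema)
  d <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  cols <- schema$columns
  need <- c(schema$endpoint, cols$name)
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  ids <- if (!is.null(schema$id) && schema$id %in% names(d))
    d[[schema$id]] else as.character(seq_len(nrow(d)))
  X <- matrix(NA_real_, nrow(d), nrow(cols),
              dimnames = list(NULL, cols$name))
  for (j in seq_len(nrow(cols))) {
    raw <- d[[cols$name[j]]]
    v <- suppressWarnings(as.numeric(raw))
    if (any(is.na(v)))
      stop("non-numeric descriptor cell '", raw[which(is.na(v))[1]],
           "' at row '", ids[which(is.na(v))[1]], "', column '",
           cols$name[j], "'")
    X[, j] <- v
  }
  zeta <- suppressWarnings(as.numeric(d[[schema$endpoint]]))
  if (any(is.na(zeta)))
    stop("non-numeric endpoint at row '", ids[which(is.na(zeta))[1]], "'")
  split <- if (!is.null(schema$split) && schema$split %in% names(d))
    d[[schema$split]] else NULL
  ref <- if (!is.null(schema$reference_pred) &&
             schema$reference_pred %in% names(d))
    as.numeric(d[[schema$reference_pred]]) else NULL
  core <- if (!is.null(schema$core_name) && schema$core_name %in% names(d))
    d[[schema$core_name]] else NULL
  coating <- if (!is.null(schema$coating_name) &&
                 schema$coating_name %in% names(d))
    d[[schema$coating_name]] else NULL
  pnp_table(X, zeta, cols, ids = ids, split = split,
            core = core, coating = coating, reference_pred = ref)
}

#' @param x a [pnp_table()] to write.
#' @param schema_path optional path for the JSON schema file.
#' @rdname read_pnp_table
#' @export
write_pnp_table <- function(x, path, schema_path = NULL) {
  stopifnot(inherits(x, "pnp_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = TRUE)
  if (!is.null(schema_path)) {
    schema <- list(id = "structure_id", endpoint = "zeta_mV",
                   split = "split", columns = x$schema)
    if (!is.null(x$core)) schema$core_name <- "core"
    if (!is.null(x$coating)) schema$coating_name <- "coating"
    if (!is.null(x$reference_pred)) schema$reference_pred <- "zeta_ref_pred_mV"
    jsonlite::write_json(schema, schema_path, auto_unbox = TRUE,
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(path)
}

#' Endpoint-sorted every-third train/validation splitter
#'
#' Sorts the samples by ascending zeta potential (ties broken by
#' `tie_break`, a deterministic secondary key) and assigns every third
#' sample of the sorted sequence (positions 3, 6, 9, ...) to the validation
#' set `V`; all others become training `T`.  This yields
#' `floor(n/3)` validation and `n - floor(n/3)` training samples and is
#' invariant to the input row order for a fixed tie-break key.
#'
#' @param x a [pnp_table()] with at least 3 samples.
#' @param tie_break numeric secondary sort key of length `nrow(x)`, or a
#'   character vector of structure ids in priority order.  Defaults to the
#'   current row order.
#' @return a relabeled copy of `x` (original row order preserved).
#' @export
#' @examples
#' tab <- pnp20()
#' resplit <- split_every_third(tab)
#' table(resplit$split)
split_every_third <- function(x, tie_break = NULL) {
  stopifnot(inherits(x, "pnp_table"))
  n <- length(x$ids)
  if (n < 3) stop("need at least 3 samples to split")
  if (is.null(tie_break)) {
    key <- seq_len(n)
  } else if (is.character(tie_break)) {
    key <- match(x$ids, tie_break)
    if (any(is.na(key))) stop("tie_break does not cover all structure ids")
  } else {
    stopifnot(length(tie_break) == n)
    key <- tie_break
  }
  ord <- order(x$zeta, key)
  lab <- rep("T", n)
  lab[ord[seq_along(ord) %% 3 == 0]] <- "V"
  x$split <- lab
  x
}

train_rows <- function(x) which(x$split == "T")
validation_rows <- function(x) which(x$split == "V")
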