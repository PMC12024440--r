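# Reading and validating parcellated time series, network atlases and
# subject/covariate tables. Panels are plain delimited numeric matrices;
# component identity travels either in a header row (components-in-columns)
# or is generated as ordinal labels.

#' Construct a time-series panel
#'
#' A panel holds one subject's component-by-time signal matrix together with
#' component labels and a flag recording whether rows have been z-scored.
#' Most users will obtain panels from [read_panel()] or [simulate_cohort()].
#'
#' @param values numeric matrix, N components x T timepoints.
#' @param subject_id single string identifying the subject.
#' @param component_ids character vector of N unique component labels;
#'   defaults to `IC001 ...`.
#' @param zscored logical; whether rows are already z-scored.
#' @return An object of class `ts_panel`.
#' @export
ts_panel <- function(values, subject_id = "subject",
                     component_ids = NULL, zscored = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_fc("panel values must be numeric")
  n <- nrow(values); t_len <- ncol(values)
  if (n < 3) stop_fc("panel needs N >= 3 components, got %d", n)
  if (t_len < 2) stop_fc("panel needs T >= 2 timepoints, got %d", t_len)
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop_fc("panel contains a missing/non-finite value at component row %d, timepoint %d",
            bad[1], bad[2])
  }
  if (is.null(component_ids)) component_ids <- sprintf("IC%03d", seq_len(n))
  component_ids <- as.character(component_ids)
  if (length(component_ids) != n) {
    stop_fc("component_ids length %d != N = %d", length(component_ids), n)
  }
  if (anyDuplicated(component_ids)) stop_fc("duplicate component ids")
  rownames(values) <- component_ids
  structure(list(subject_id = as.character(subject_id), values = values,
                 component_ids = component_ids, zscored = isTRUE(zscored)),
            class = "ts_panel")
}

#' @export
print.ts_panel <- function(x, ...) {
  cat(sprintf("ts_panel '%s': %d components x %d timepoints (%sz-scored)\n",
              x$subject_id, nrow(x$values), ncol(x$values),
              if (x$zscored) "" else "not "))
  invisible(x)
}

#' Read a parcellated time-series panel from delimited text
#'
#' Orientation is an explicit contract, never guessed from the matrix shape.
#' With `orientation = "columns"` the optional header row supplies component
#' ids; with `orientation = "rows"` a header (if declared) is ignored and
#' ordinal ids are generated. Any missing or non-numeric cell is rejected
#' with its location.
#'
#' @param path file path to a delimited numeric matrix.
#' @param delimiter field separator, default tab.
#' @param orientation `"rows"` (components in rows, default) or `"columns"`.
#' @param header `"auto"`, `TRUE` or `FALSE`. `"auto"` treats the first line
#'   as a header when it contains any non-numeric token.
#' @param subject_id subject label; defaults to the file name without
#'   extension.
#' @return A `ts_panel` (not yet z-scored).
#' @export
read_panel <- function(path, delimiter = "\t",
                       orientation = c("rows", "columns"),
                       header = "auto", subject_id = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_fc("panel file not found: %s", path)
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_fc("panel file is empty: %s", path)
  cells <- strsplit(lines, delimiter, fixed = TRUE)
  ncells <- lengths(cells)
  if (length(unique(ncells)) != 1) {
    stop_fc("ragged panel file %s: line 1 has %d fields, line %d has %d",
            path, ncells[1], which(ncells != ncells[1])[1],
            ncells[which(ncells != ncells[1])[1]])
  }
  first_num <- suppressWarnings(as.numeric(cells[[1]]))
  has_header <- if (identical(header, "auto")) anyNA(first_num) else isTRUE(header)
  ids <- NULL
  if (has_header) {
    ids <- trimws(cells[[1]])
    cells <- cells[-1]
    if (!length(cells)) stop_fc("panel file %s has a header but no data", path)
  }
  mat <- matrix(NA_real_, nrow = length(cells), ncol = ncells[1])
  for (r in seq_along(cells)) {
    v <- suppressWarnings(as.numeric(cells[[r]]))
    if (anyNA(v)) {
      c0 <- which(is.na(v))[1]
      raw <- trimws(cells[[r]][c0])
      kind <- if (toupper(raw) %in% c("NA", "NAN", "")) "missing" else "non-numeric"
      stop_fc("%s cell '%s' in %s at data row %d, column %d",
              kind, raw, path, r, c0)
    }
    mat[r, ] <- v
  }
  if (orientation == "columns") {
    mat <- t(mat)
  } else {
    ids <- NULL # a header on a components-in-rows file labels timepoints
  }
  ts_panel(mat, subject_id = subject_id, component_ids = ids)
}

#' Write a panel as delimited text
#'
#' Writes timepoints in rows and components in columns with a header row of
#' component ids — the layout [read_panel()] reads back with
#' `orientation = "columns"`. Values are written with 15 significant digits.
#'
#' @param panel a `ts_panel`.
#' @param path output file path.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, delimiter = "\t") {
  stopifnot(inherits(panel, "ts_panel"))
  m <- t(panel$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(panel$component_ids, collapse = delimiter), con)
  writeLines(apply(m, 1, function(r) paste(fmt_num(r), collapse = delimiter)),
             con)
  invisible(path)
}

#' Z-score a panel row-wise
#'
#' Each component series is transformed to (x - mean) / sd using the
#' population variance convention (divide by T, not T - 1). Under that
#' convention the time average of the product of two z-scored rows equals
#' their Pearson correlation exactly, an identity the edge-construction
#' tests rely on.
#'
#' @param panel a `ts_panel` not yet z-scored.
#' @return The z-scored `ts_panel`.
#' @export
zscore_panel <- function(panel) {
  stopifnot(inherits(panel, "ts_panel"))
  if (panel$zscored) stop_fc("panel '%s' is already z-scored", panel$subject_id)
  x <- panel$values
  mu <- rowMeans(x)
  xc <- x - mu
  sdv <- sqrt(rowMeans(xc^2))
  if (any(sdv == 0)) {
    stop_fc("zero variance: component '%s' is constant, z-score undefined",
            panel$component_ids[which(sdv == 0)[1]])
  }
  panel$values <- xc / sdv
  panel$zscored <- TRUE
  panel
}

#' Construct a network atlas
#'
#' @param component_id character vector of component labels.
#' @param network character vector of network names, same length.
#' @return An object of class `network_atlas` with fields `mapping` (named
#'   character vector component -> network) and `network_order` (unique
#'   networks in first-appearance order).
#' @export
network_atlas <- function(component_id, network) {
  component_id <- as.character(component_id)
  network <- as.character(network)
  stopifnot(length(component_id) == length(network))
  if (anyDuplicated(component_id)) {
    stop_fc("duplicate component id in atlas: '%s'",
            component_id[anyDuplicated(component_id)])
  }
  mapping <- stats::setNames(network, component_id)
  structure(list(mapping = mapping, network_order = unique(network)),
            class = "network_atlas")
}

#' Read a component-to-network atlas
#'
#' Expects a delimited table with a header naming at least `component_id`
#' and `network`.
#'
#' @param path file path.
#' @param delimiter field separator.
#' @return A `network_atlas`.
#' @export
read_atlas <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop_fc("atlas file not found: %s", path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          colClasses = "character", check.names = FALSE)
  need <- c("component_id", "network")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_fc("atlas %s lacks column(s): %s", path,
                            paste(miss, collapse = ", "))
  network_atlas(df$component_id, df$network)
}

# Every panel component must appear in the atlas (exact string match).
check_atlas_covers <- function(atlas, component_ids) {
  miss <- setdiff(component_ids, names(atlas$mapping))
  if (length(miss)) {
    stop_fc("component '%s' missing from atlas", miss[1])
  }
  invisible(TRUE)
}

#' Construct a subject table
#'
#' @param df data.frame with columns `subject_id`, `group`, and numeric
#'   covariate columns.
#' @return An object of class `subject_table` (a validated data.frame).
#' @export
subject_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("subject_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_fc("subject table lacks column(s): %s",
                            paste(miss, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  df$group <- as.character(df$group)
  if (anyDuplicated(df$subject_id)) {
    stop_fc("duplicate subject_id: '%s'", df$subject_id[anyDuplicated(df$subject_id)])
  }
  g <- sort(unique(df$group))
  if (length(g) != 2) {
    stop_fc("subject table must have exactly 2 group labels, found %d (%s)",
            length(g), paste(g, collapse = ", "))
  }
  covs <- setdiff(names(df), need)
  for (cv in covs) {
    df[[cv]] <- as.numeric(df[[cv]])
    if (anyNA(df[[cv]])) stop_fc("covariate '%s' has missing values", cv)
  }
  class(df) <- c("subject_table", "data.frame")
  attr(df, "groups") <- g
  df
}

#' Read a subject/covariate table
#'
#' Delimited text with header columns `subject_id`, `group`, plus any number
#' of numeric covariate columns (age, sex code, education, symptom scores).
#'
#' @param path file path.
#' @param delimiter field separator.
#' @return A `subject_table`.
#' @export
read_subjects <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop_fc("subject file not found: %s", path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  subject_table(df)
}
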