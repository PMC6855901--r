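#' Abundance matrix with an explicit detection mask
#'
#' The single object flowing through preprocessing: a metabolites x samples
#' matrix of non-negative total ion counts (TIC, arbitrary units) together
#' with a same-shape logical mask recording which cells were actually
#' measured. Cells below the limit of detection carry `NA` in `values` (never
#' 0 -- zero is a legal ion count after scaling and must not be conflated
#' with censoring) until [impute_lod()] fills them in. A stage tag records
#' the last preprocessing step applied so that the pipeline order
#' raw -> scaled -> imputed -> decay_corrected -> adjusted is enforced.
#'
#' @param values numeric matrix, metabolites in rows (rownames = metabolite
#'   ids), samples in columns (colnames = sample ids). Undetected cells `NA`.
#' @param detected logical matrix of the same shape; `TRUE` where measured.
#'   Defaults to `!is.na(values)`.
#' @param stage one of `"raw"`, `"scaled"`, `"imputed"`, `"decay_corrected"`,
#'   `"adjusted"`.
#' @return An object of class `"abund"`.
#' @examples
#' m <- matrix(c(10, NA, 30, 40), 2, 2,
#'             dimnames = list(c("m1", "m2"), c("s1", "s2")))
#' a <- abund(m)
#' abund_stage(a)
#' @export
abund <- function(values, detected = !is.na(values), stage = "raw") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have metabolite rownames and sample colnames",
         call. = FALSE)
  }
  stage <- match.arg(stage, abund_stages())
  if (!is.logical(detected) || !identical(dim(detected), dim(values))) {
    stop("`detected` must be a logical matrix with the shape of `values`",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicated metabolite id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    stop("duplicated sample id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(values) & values < 0)) {
    bad <- which(!is.na(values) & values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at metabolite '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]),
         call. = FALSE)
  }
  if (any(is.na(values) & detected)) {
    stop("detected cells must carry a numeric value", call. = FALSE)
  }
  dimnames(detected) <- dimnames(values)
  structure(list(values = values, detected = detected, stage = stage),
            class = "abund")
}

abund_stages <- function() {
  c("raw", "scaled", "imputed", "decay_corrected", "adjusted")
}

#' @rdname abund
#' @param x an `abund` object.
#' @export
is_abund <- function(x) inherits(x, "abund")

#' @rdname abund
#' @export
abund_stage <- function(x) x$stage

set_stage <- function(x, stage) {
  x$stage <- match.arg(stage, abund_stages())
  x
}

require_stage <- function(x, allowed, op) {
  if (!is_abund(x)) stop(op, ": input must be an `abund` object", call. = FALSE)
  if (!x$stage %in% allowed) {
    stop(sprintf("%s: expected stage %s but matrix is at stage '%s'",
                 op, paste(sQuote(allowed), collapse = " or "), x$stage),
         call. = FALSE)
  }
  invisible(x)
}

#' @export
dim.abund <- function(x) dim(x$values)

#' @export
print.abund <- function(x, ...) {
  cat(sprintf("<abund> %d metabolites x %d samples, stage '%s'\n",
              nrow(x$values), ncol(x$values), x$stage))
  cat(sprintf("  detected cells: %d / %d (%.1f%%)\n",
              sum(x$detected), length(x$detected),
              100 * mean(x$detected)))
  invisible(x)
}

#' Read / write the abundance CSV dialect
#'
#' Comma-separated, UTF-8, one id column plus one column (or row) per sample.
#' Blank cells, empty strings and `NA` denote non-detection; they become `NA`
#' values with `detected = FALSE`. Because the layout of deposited matrices
#' varies, orientation is explicit rather than guessed, with
#' `metabolites_as_rows` as the documented default.
#'
#' @param path CSV file path.
#' @param orientation `"metabolites_as_rows"` (default) or
#'   `"samples_as_rows"`.
#' @return [read_abundance_csv()] returns an `abund` at stage `"raw"`;
#'   [write_abundance_csv()] returns `path` invisibly. A write/read round
#'   trip preserves values and mask exactly.
#' @export
read_abundance_csv <- function(path,
                               orientation = c("metabolites_as_rows",
                                               "samples_as_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(raw) < 2) stop("abundance CSV needs an id column plus data", call. = FALSE)
  ids <- raw[[1]]
  body <- raw[, -1, drop = FALSE]
  cells <- as.matrix(body)
  cells[cells == ""] <- NA_character_
  suppressWarnings(num <- matrix(as.numeric(cells), nrow(cells), ncol(cells)))
  bad <- which(is.na(num) & !is.na(cells) & toupper(trimws(cells)) != "NA",
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell '%s' at row id '%s', column '%s'",
                 cells[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(body)[bad[1, 2]]), call. = FALSE)
  }
  num[toupper(trimws(cells)) == "NA"] <- NA_real_
  rownames(num) <- ids
  colnames(num) <- colnames(body)
  if (orientation == "samples_as_rows") num <- t(num)
  abund(num, stage = "raw")
}

#' @rdname read_abundance_csv
#' @param x an `abund` object to write.
#' @param id_column header for the first (id) column.
#' @export
write_abundance_csv <- function(x, path, id_column = "metabolite_id") {
  stopifnot(is_abund(x))
  # %.17g keeps doubles bit-exact through the round trip
  chr <- matrix(ifelse(is.na(x$values), NA_character_,
                       sprintf("%.17g", x$values)),
                nrow(x$values), dimnames = dimnames(x$values))
  df <- data.frame(chr, check.names = FALSE)
  df <- cbind(stats::setNames(data.frame(rownames(x$values),
                                         stringsAsFactors = FALSE),
                              id_column), df)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Gestational age string conversion
#'
#' Clinical gestational age notation `"<w>w<d>d"` (e.g. `"12w4d"`) is
#' converted to decimal weeks as `w + d/7`; plain numeric strings pass
#' through. [format_gestational_age()] is the exact inverse for whole
#' weeks-plus-days values.
#'
#' @param x character (or numeric) vector of gestational ages.
#' @return numeric vector of decimal weeks (`NA` stays `NA`).
#' @examples
#' parse_gestational_age(c("12w4d", "8w0d", "10.5"))
#' @export
parse_gestational_age <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  blank <- is.na(x) | x == "" | toupper(x) == "NA"
  wd <- grepl("^[0-9]+w[0-9]+d$", x)
  num <- !blank & !wd & grepl("^[0-9]*\\.?[0-9]+$", x)
  out[num] <- as.numeric(x[num])
  if (any(wd)) {
    w <- as.numeric(sub("w.*$", "", x[wd]))
    d <- as.numeric(sub("^.*w([0-9]+)d$", "\\1", x[wd]))
    if (any(d > 6)) stop("gestational-age days must be 0-6: ",
                         paste(x[wd][d > 6], collapse = ", "), call. = FALSE)
    out[wd] <- w + d / 7
  }
  bad <- !blank & !wd & !num
  if (any(bad)) {
    stop("unparsable gestational age: ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' @rdname parse_gestational_age
#' @param weeks numeric decimal weeks.
#' @export
format_gestational_age <- function(weeks) {
  w <- floor(weeks + 1e-9)
  d <- round((weeks - w) * 7)
  carry <- !is.na(d) & d >= 7
  w[carry] <- w[carry] + 1
  d[carry] <- 0
  ifelse(is.na(weeks), NA_character_, sprintf("%dw%dd", w, d))
}

#' Read sample metadata / metabolite annotation tables
#'
#' Metadata columns: `sample_id, group, gestational_age, run_day,
#' storage_time_months, maternal_age, ethnicity, smoker, replicate_group`.
#' Annotation columns: `metabolite_id, display_name, platform, super_pathway,
#' sub_pathway` (missing sub-pathways become `"unannotated"`).
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  required <- c("sample_id", "group")
  missing <- setdiff(required, names(meta))
  if (length(missing)) stop("metadata lacks column(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  validate_metadata(normalize_metadata(meta))
}

normalize_metadata <- function(meta) {
  meta <- tibble::as_tibble(meta)
  if (!"gestational_age" %in% names(meta)) meta$gestational_age <- NA_real_
  for (col in c("run_day", "ethnicity", "replicate_group")) {
    if (!col %in% names(meta)) meta[[col]] <- NA_character_
  }
  for (col in c("storage_time_months", "maternal_age")) {
    if (!col %in% names(meta)) meta[[col]] <- NA_real_
  }
  if (!"smoker" %in% names(meta)) meta$smoker <- NA
  dplyr::mutate(meta,
    sample_id = as.character(.data$sample_id),
    group = as.character(.data$group),
    gestational_age = parse_gestational_age(.data$gestational_age),
    run_day = as.character(.data$run_day),
    storage_time_months = as.numeric(.data$storage_time_months),
    maternal_age = as.numeric(.data$maternal_age),
    ethnicity = as.character(.data$ethnicity),
    smoker = as.logical(.data$smoker),
    replicate_group = as.character(.data$replicate_group)
  )
}

validate_metadata <- function(meta) {
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicated sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  ok_groups <- c("pregnant", "non_pregnant", "reference", "replicate")
  bad <- setdiff(unique(meta$group), ok_groups)
  if (length(bad)) stop("unknown group label(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  preg <- meta$group == "pregnant"
  if (any(preg & is.na(meta$gestational_age))) {
    stop("pregnant sample(s) without gestational age: ",
         paste(meta$sample_id[preg & is.na(meta$gestational_age)],
               collapse = ", "), call. = FALSE)
  }
  ga <- meta$gestational_age[preg]
  if (any(ga <= 0 | ga >= 45)) {
    stop("gestational age out of (0, 45) weeks", call. = FALSE)
  }
  if (any(!preg & !is.na(meta$gestational_age) &
            meta$group %in% c("non_pregnant", "reference"))) {
    stop("gestational age given for a non-pregnant sample", call. = FALSE)
  }
  if (any(!is.na(meta$storage_time_months) & meta$storage_time_months < 0)) {
    stop("negative storage time", call. = FALSE)
  }
  meta
}

#' @rdname read_sample_metadata
#' @export
read_annotation <- function(path) {
  ann <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  required <- c("metabolite_id", "sub_pathway")
  missing <- setdiff(required, names(ann))
  if (length(missing)) stop("annotation lacks column(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(ann$metabolite_id)) {
    stop("duplicated metabolite_id in annotation", call. = FALSE)
  }
  for (col in c("display_name", "platform", "super_pathway")) {
    if (!col %in% names(ann)) ann[[col]] <- NA_character_
  }
  ann$sub_pathway[is.na(ann$sub_pathway) | ann$sub_pathway == ""] <- "unannotated"
  tibble::as_tibble(ann[, c("metabolite_id", "display_name", "platform",
                            "super_pathway", "sub_pathway")])
}

#' Align an abundance matrix with its sample metadata
#'
#' Reorders the matrix columns to the metadata row order (the canonical
#' sample ordering throughout the pipeline, so outputs are deterministic)
#' and parses gestational-age strings to decimal weeks. Every matrix column
#' must have a metadata row.
#'
#' @param x an `abund` object.
#' @param meta a metadata data frame (as from [read_sample_metadata()], or
#'   any data frame with at least `sample_id` and `group`).
#' @return A list with elements `abund` (columns in metadata order) and
#'   `metadata` (tibble restricted to samples present in the matrix).
#' @export
join_metadata <- function(x, meta) {
  stopifnot(is_abund(x))
  meta <- validate_metadata(normalize_metadata(meta))
  orphans <- setdiff(colnames(x$values), meta$sample_id)
  if (length(orphans)) {
    stop("samples missing from metadata: ", paste(orphans, collapse = ", "),
         call. = FALSE)
  }
  meta <- dplyr::filter(meta, .data$sample_id %in% colnames(x$values))
  x$values <- x$values[, meta$sample_id, drop = FALSE]
  x$detected <- x$detected[, meta$sample_id, drop = FALSE]
  list(abund = x, metadata = meta)
}
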