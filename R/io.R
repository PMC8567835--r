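#' Functional-network labels recognised by the package
#'
#' The seven resting-state cortical networks (Yeo et al. parcellation) plus
#' a subcortical set.
#'
#' @return Character vector of the 8 allowed network labels.
#' @export
network_labels <- function() {
  c("Visual", "Somatomotor", "DorsalAttention", "VentralAttention",
    "Limbic", "Frontoparietal", "Default", "Subcortical")
}

split_fields <- function(lines) {
  # delimiter auto-detection among tab / comma / whitespace
  probe <- lines[nzchar(trimws(lines))][1]
  delim <- if (grepl("\t", probe)) "\t" else if (grepl(",", probe)) ","
           else "[[:space:]]+"
  lapply(trimws(lines), function(l) strsplit(l, delim)[[1]])
}

#' Read a connectome matrix or time-series matrix from delimited text
#'
#' Reads a rectangular numeric matrix from a TSV/CSV/whitespace-delimited
#' file (the delimiter is auto-detected) with an optional header row of
#' region identifiers, and validates it against the invariants of the
#' requested kind: `"structural"` (symmetric, zero diagonal, nonnegative
#' mm lengths), `"functional"` (symmetric, nonnegative MI in bits) or
#' `"timeseries"` (any rectangular N x T matrix, T >= 2).
#'
#' @param path File path.
#' @param kind One of `"structural"`, `"functional"`, `"timeseries"`.
#' @return A [structural_connectome()], [functional_connectome()], or a
#'   plain numeric matrix with region-id rownames for `"timeseries"`.
#' @export
read_matrix <- function(path,
                        kind = c("structural", "functional", "timeseries")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(sprintf("empty file: %s", path))
  fields <- split_fields(lines)
  ncols <- lengths(fields)
  first_numeric <- !anyNA(suppressWarnings(as.numeric(fields[[1]])))
  region_ids <- NULL
  if (!first_numeric) {
    region_ids <- fields[[1]]
    fields <- fields[-1]
    ncols <- ncols[-1]
    if (!length(fields)) abort(sprintf("no data rows in %s", path))
  }
  if (length(unique(ncols)) != 1) {
    abort(sprintf("ragged rows in %s: %d vs %d columns.",
                  path, ncols[1], max(ncols)))
  }
  vals <- suppressWarnings(lapply(fields, as.numeric))
  for (i in seq_along(vals)) {
    if (anyNA(vals[[i]])) {
      j <- which(is.na(vals[[i]]))[1]
      abort(sprintf("non-numeric cell at data row %d, column %d of %s: '%s'",
                    i, j, path, fields[[i]][j]))
    }
  }
  m <- do.call(rbind, vals)
  if (!is.null(region_ids)) {
    if (kind != "timeseries" && length(region_ids) != ncol(m)) {
      abort(sprintf("header of %s has %d ids but the matrix has %d columns.",
                    path, length(region_ids), ncol(m)))
    }
    if (kind == "timeseries") {
      # for time series a header would label timepoints; ignore it
      region_ids <- NULL
    }
  }
  switch(kind,
    structural = structural_connectome(m, region_ids),
    functional = functional_connectome(m, region_ids),
    timeseries = {
      if (ncol(m) < 2) abort("time series must have T >= 2 timepoints.")
      rownames(m) <- paste0("R", seq_len(nrow(m)))
      m
    }
  )
}

fmt_num <- function(x) {
  # shortest decimal representation that round-trips a double
  out <- character(length(x))
  bad <- !is.finite(x)
  out[bad] <- as.character(x[bad])
  if (any(!bad)) {
    v <- x[!bad]
    long <- sprintf("%.17g", v)
    short <- sprintf("%.15g", v)
    out[!bad] <- ifelse(as.numeric(short) == v, short, long)
  }
  out
}

#' Write a matrix (or connectome) as tab-delimited text
#'
#' Written files carry a header row of region ids and round-trip through
#' [read_matrix()] exactly (numbers are printed with enough digits to
#' recover the double).
#'
#' @param x A matrix, [structural_connectome()] or [functional_connectome()].
#' @param path Output file path.
#' @param header Write the region-id header row (default `TRUE`; disabled
#'   automatically for time-series matrices without square shape).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, header = TRUE) {
  m <- if (inherits(x, "structural_connectome")) x$lengths
       else if (inherits(x, "functional_connectome")) x$mi
       else as.matrix(x)
  con <- file(path, "wb")  # binary mode: fixed "\n", byte-stable output
  on.exit(close(con))
  if (header && nrow(m) == ncol(m) && !is.null(colnames(m))) {
    writeLines(paste(colnames(m), collapse = "\t"), con)
  }
  body <- apply(m, 1, function(r) paste(fmt_num(r), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read a parcellation table
#'
#' A parcellation maps every region to exactly one functional network (the
#' seven Yeo cortical networks plus `"Subcortical"`) and a hemisphere. The
#' file is a delimited table with header columns `region`, `network`,
#' `hemisphere`; region order in the file is authoritative and preserved.
#'
#' @param path File path. Defaults to the packaged synthetic 374-region
#'   atlas (see [default_parcellation()]).
#' @return A tibble with columns `region`, `network`, `hemisphere`.
#' @export
read_parcellation <- function(path = NULL) {
  if (is.null(path)) return(default_parcellation())
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- split_fields(lines)
  hdr <- tolower(fields[[1]])
  need <- c("region", "network", "hemisphere")
  if (!all(need %in% hdr)) {
    abort("parcellation table must have header columns region, network, hemisphere.")
  }
  idx <- match(need, hdr)
  rows <- fields[-1]
  bad <- which(lengths(rows) < max(idx))
  if (length(bad)) abort(sprintf("short row %d in %s", bad[1] + 1, path))
  tab <- tibble(
    region = vapply(rows, `[[`, "", idx[1]),
    network = vapply(rows, `[[`, "", idx[2]),
    hemisphere = vapply(rows, `[[`, "", idx[3])
  )
  validate_parcellation(tab)
}

#' @rdname read_parcellation
#' @param tab A data frame with columns `region`, `network`, `hemisphere`.
#' @export
validate_parcellation <- function(tab) {
  tab <- as_tibble(tab)
  need <- c("region", "network", "hemisphere")
  if (!all(need %in% names(tab))) {
    abort("parcellation needs columns region, network, hemisphere.")
  }
  unknown <- setdiff(unique(tab$network), network_labels())
  if (length(unknown)) {
    abort(sprintf(
      "unknown network label(s) %s; allowed labels are: %s",
      paste(sQuote(unknown), collapse = ", "),
      paste(network_labels(), collapse = ", ")
    ))
  }
  if (anyDuplicated(tab$region)) abort("duplicated region ids in parcellation.")
  tab[need]
}

#' Packaged default parcellation (synthetic 374-region atlas)
#'
#' A schematic stand-in for the 374-region atlas used in large-scale
#' connectome studies: 360 cortical regions (180 per hemisphere, allocated
#' across the seven Yeo networks in realistic proportions, with synthetic
#' region names) plus the 14 HCP subcortical regions under their anatomical
#' names. The table is synthetic: cortical region names are placeholders,
#' not the HCP-MMP1.0 labels.
#'
#' @return A tibble with 374 rows and columns `region`, `network`,
#'   `hemisphere`.
#' @export
default_parcellation <- function() {
  path <- system.file("extdata", "atlas374_synthetic.tsv",
                      package = "braincomm", mustWork = TRUE)
  read_parcellation_file_raw(path)
}

read_parcellation_file_raw <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_parcellation(tab)
}

#' Group-average structural connectome
#'
#' Averages subject-level structural connectomes into a group reference.
#' Because a zero entry encodes an absent connection (not a length of 0 mm),
#' entry (i, j) of the average is the mean streamline length over the
#' subjects in which the edge is present; an edge is retained only if
#' present in at least `min_fraction` of subjects (default: one subject
#' suffices).
#'
#' @param connectomes List of [structural_connectome()] objects on an
#'   identical region set.
#' @param min_fraction Minimum fraction of subjects in which an edge must be
#'   nonzero to be kept (default `0`, i.e. >= 1 subject).
#' @return A [structural_connectome()].
#' @export
group_average_structural <- function(connectomes, min_fraction = 0) {
  if (!length(connectomes)) abort("need at least one connectome.")
  if (inherits(connectomes, "structural_connectome")) {
    connectomes <- list(connectomes)
  }
  ref <- connectomes[[1]]
  for (x in connectomes) {
    if (!inherits(x, "structural_connectome")) {
      abort("all elements must be structural_connectome objects.")
    }
    check_same_regions(ref, x, "structural connectomes")
  }
  nsub <- length(connectomes)
  total <- Reduce(`+`, lapply(connectomes, `[[`, "lengths"))
  npresent <- Reduce(`+`, lapply(connectomes, function(x) (x$lengths > 0) * 1))
  keep <- npresent >= max(1, ceiling(min_fraction * nsub))
  avg <- matrix(0, nrow(total), ncol(total))
  avg[keep] <- total[keep] / npresent[keep]
  structural_connectome(avg, ref$region_ids)
}
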