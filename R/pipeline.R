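#' Helper correlation structures for the synthetic Gaussian generator
#'
#' @param n Number of regions.
#' @param kind `"identity"` (independent regions), `"block"`
#'   (block-diagonal communities with common within-block correlation) or
#'   `"chain"` (AR(1)-style decay, `corr(i, j) = rho^|i-j|`).
#' @param rho Correlation parameter in (-1, 1).
#' @param block_size Community size for `kind = "block"`.
#' @return N x N correlation matrix.
#' @export
synth_correlation <- function(n, kind = c("identity", "block", "chain"),
                              rho = 0.6, block_size = 4) {
  kind <- match.arg(kind)
  if (abs(rho) >= 1) abort("|rho| must be < 1.")
  switch(kind,
    identity = diag(n),
    chain = rho^abs(outer(seq_len(n), seq_len(n), `-`)),
    block = {
      blocks <- ceiling(seq_len(n) / block_size)
      m <- (outer(blocks, blocks, `==`)) * rho
      diag(m) <- 1
      m
    }
  )
}

#' Full communication analysis of one structural-functional pair
#'
#' Runs the whole framework in memory: mutual-information functional
#' connectome (when raw time series are given), fiber-length shortest
#' paths, path processing scores, regime classification, path broadcasting
#' strengths, per-regime nodal broadcasting strengths, and (when a
#' parcellation is supplied) network stratification of the regimes.
#'
#' @param sc A [structural_connectome()].
#' @param fc A [functional_connectome()], or `NULL` to estimate one from
#'   `timeseries`.
#' @param timeseries Raw N x T regional time series (used when `fc` is
#'   `NULL`).
#' @param parcellation Optional parcellation tibble for stratification.
#' @param scheme [binning_scheme()] for MI estimation.
#' @param boundaries [regime_boundaries()]; the package default is the
#'   published relay interval \[-0.04, 0.07\] bits.
#' @param pps_mode Passed to [add_pps()].
#' @param exclude_incoming Passed to [add_pbs()].
#' @return Object of class `comm_analysis`: list with `sc`, `fc`,
#'   `parcellation`, `boundaries`, `pairs` (the fully scored path table),
#'   `wbs` (per-regime nodal broadcasting strengths, long tibble) and
#'   `stratification` (or `NULL`). Use [tidy()] / [glance()] to extract
#'   tibbles.
#' @examples
#' fx <- toy_fixture()
#' ca <- communication_analysis(fx$sc, fx$fc, parcellation = fx$parcellation)
#' glance(ca)
#' @export
communication_analysis <- function(sc, fc = NULL, timeseries = NULL,
                                   parcellation = NULL,
                                   scheme = binning_scheme(),
                                   boundaries = regime_boundaries(),
                                   pps_mode = "anchor",
                                   exclude_incoming = FALSE) {
  if (is.null(fc)) {
    if (is.null(timeseries)) abort("provide `fc` or `timeseries`.")
    if (nrow(timeseries) != length(sc$region_ids)) {
      abort("time series and structural connectome disagree on N.")
    }
    rownames(timeseries) <- sc$region_ids
    fc <- mi_connectome(timeseries, scheme)
  }
  check_same_regions(sc, fc, "connectomes")
  paths <- shortest_paths(sc)
  scored <- add_pps(paths, fc, mode = pps_mode)
  scored <- classify_regimes(scored, boundaries)
  scored <- add_pbs(scored, fc, sc, exclude_incoming = exclude_incoming)
  wbs <- bind_rows(lapply(c("direct", "relay", "transducted"),
                          function(r) broadcast_strengths(scored, r)))
  strat <- NULL
  if (!is.null(parcellation)) {
    strat <- regime_by_network(scored, parcellation)
  }
  structure(
    list(sc = sc, fc = fc, parcellation = parcellation,
         boundaries = boundaries, pairs = scored, wbs = wbs,
         stratification = strat),
    class = "comm_analysis"
  )
}

#' @export
print.comm_analysis <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<comm_analysis> %d regions, %d ordered pairs\n  regimes: direct %d, absent %d, relay %d, transducted %d, disconnected %d\n  relay boundaries [%g, %g] bits\n",
    g$n_regions, g$n_pairs, g$n_direct, g$n_absent, g$n_relay,
    g$n_transducted, g$n_disconnected, g$lower, g$upper
  ))
  invisible(x)
}

resolve_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    structural = NULL, timeseries = NULL, functional = NULL,
    parcellation = NULL, out_dir = NULL,
    mi = list(bin_width = 0.5, range = c(-3.5, 3.5)),
    regimes = list(lower = -0.04, upper = 0.07,
                   estimate = FALSE, network = "Default",
                   percentiles = c(5, 95)),
    pps_mode = "anchor", exclude_incoming = FALSE, seed = 1
  )
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$structural)) abort("config: `structural` input path is required.")
  if (is.null(cfg$out_dir)) abort("config: `out_dir` is required.")
  if (is.null(cfg$timeseries) && is.null(cfg$functional)) {
    abort("config: provide `timeseries` or `functional`.")
  }
  cfg
}

write_pairs_tsv <- function(pairs, region_ids, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(
    c("source", "target", "connected", "hops", "length_mm", "pps",
      "regime", "pbs_raw", "pbs"), collapse = "\t"), con)
  numfmt <- function(x) ifelse(is.na(x), "NA", fmt_num(x))
  writeLines(paste(
    region_ids[pairs$source], region_ids[pairs$target],
    ifelse(pairs$connected, "TRUE", "FALSE"),
    ifelse(is.na(pairs$hops), "NA", as.character(pairs$hops)),
    numfmt(pairs$length_mm), numfmt(pairs$pps),
    as.character(pairs$regime), numfmt(pairs$pbs_raw), numfmt(pairs$pbs),
    sep = "\t"), con)
  invisible(path)
}

write_jsonl_paths <- function(pairs, region_ids, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (k in seq_len(nrow(pairs))) {
    rec <- list(
      source = region_ids[pairs$source[k]],
      target = region_ids[pairs$target[k]],
      connected = pairs$connected[k]
    )
    if (pairs$connected[k]) {
      rec$hops <- pairs$hops[k]
      rec$length_mm <- pairs$length_mm[k]
      rec$path <- region_ids[pairs$path[[k]]]
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Run the full analysis from a configuration and write all artifacts
#'
#' Reads the inputs named in `config` (a YAML file path or an equivalent
#' list), runs [communication_analysis()], and writes the functional
#' connectome, the shortest paths (JSON lines), the fully scored pair
#' table, per-regime nodal broadcasting strengths, the network
#' stratification, and a manifest echoing the resolved configuration and
#' package version. All outputs are deterministic: rerunning with the same
#' configuration produces byte-identical files.
#'
#' Config keys: `structural` (path, required), `timeseries` or
#' `functional` (path, one required), `parcellation` (path; packaged
#' default atlas when omitted), `out_dir` (required),
#' `mi$bin_width`, `mi$range`, `regimes$lower`, `regimes$upper`,
#' `regimes$estimate` (when `TRUE`, boundaries are re-estimated from the
#' within-`regimes$network` PPS distribution at `regimes$percentiles`),
#' `pps_mode`, `exclude_incoming`, `seed`.
#'
#' @param config YAML file path or named list.
#' @return The `comm_analysis` object, invisibly; side effect: files under
#'   `out_dir`.
#' @export
run_full_analysis <- function(config) {
  cfg <- resolve_config(config)
  sc <- read_matrix(cfg$structural, "structural")
  scheme <- binning_scheme(cfg$mi$bin_width, unlist(cfg$mi$range))
  if (!is.null(cfg$functional)) {
    fc <- read_matrix(cfg$functional, "functional")
    if (is.null(rownames(fc$mi)) ||
        all(fc$region_ids == paste0("R", seq_along(fc$region_ids)))) {
      fc <- functional_connectome(fc$mi, sc$region_ids, binning = NULL)
    }
    ts <- NULL
  } else {
    fc <- NULL
    ts <- read_matrix(cfg$timeseries, "timeseries")
  }
  parc <- if (is.null(cfg$parcellation)) default_parcellation()
          else read_parcellation(cfg$parcellation)
  if (!all(sc$region_ids %in% parc$region)) {
    parc_use <- NULL  # stratification skipped when the atlas does not cover the data
  } else {
    parc_use <- parc
  }
  boundaries <- regime_boundaries(cfg$regimes$lower, cfg$regimes$upper,
                                  provenance = "run configuration")
  ca <- communication_analysis(
    sc, fc = fc, timeseries = ts, parcellation = parc_use,
    scheme = scheme, boundaries = boundaries,
    pps_mode = cfg$pps_mode, exclude_incoming = cfg$exclude_incoming
  )
  if (isTRUE(cfg$regimes$estimate)) {
    if (is.null(parc_use)) {
      abort("regimes$estimate = TRUE requires a parcellation covering the data.")
    }
    boundaries <- estimate_boundaries(ca$pairs, parc_use,
                                      network = cfg$regimes$network,
                                      percentiles = unlist(cfg$regimes$percentiles))
    ca <- communication_analysis(
      sc, fc = ca$fc, parcellation = parc_use, scheme = scheme,
      boundaries = boundaries, pps_mode = cfg$pps_mode,
      exclude_incoming = cfg$exclude_incoming
    )
  }
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_matrix(ca$fc, file.path(out, "functional_connectome.tsv"))
  write_jsonl_paths(ca$pairs, sc$region_ids, file.path(out, "paths.jsonl"))
  write_pairs_tsv(ca$pairs, sc$region_ids, file.path(out, "pairs.tsv"))
  write_tibble_tsv(ca$wbs[c("regime", "region", "wbs_sender",
                            "wbs_receiver", "wbs")],
                   file.path(out, "wbs.tsv"))
  if (!is.null(ca$stratification)) {
    write_tibble_tsv(
      ca$stratification[c("regime", "source_network", "target_network",
                          "n", "pct")],
      file.path(out, "stratification.tsv")
    )
  }
  manifest <- list(
    package = "braincomm",
    version = as.character(utils::packageVersion("braincomm")),
    boundaries = list(lower = ca$boundaries$lower,
                      upper = ca$boundaries$upper,
                      provenance = ca$boundaries$provenance),
    config = cfg
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(ca)
}

write_tibble_tsv <- function(tab, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(names(tab), collapse = "\t"), con)
  cols <- lapply(tab, function(col) {
    if (is.numeric(col) && !is.integer(col)) {
      ifelse(is.na(col), "NA", fmt_num(col))
    } else {
      as.character(col)
    }
  })
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Write a synthetic dataset (structural, time series, atlas) to disk
#'
#' Emits `sc.tsv`, `ts.tsv` and `atlas.tsv` under `out_dir`: a spatially
#' embedded structural connectome, Gaussian regional time series with a
#' chosen correlation structure, and a matching parcellation table cycling
#' through the 8 network labels.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_regions,n_timepoints Problem size.
#' @param seed Integer seed (fully determines the dataset).
#' @param radius,box Structural geometry, see [synth_structural()].
#' @param corr_kind,rho,block_size Correlation structure, see
#'   [synth_correlation()].
#' @return Named character vector of the three written paths, invisibly.
#' @export
write_synthetic_dataset <- function(out_dir, n_regions = 20,
                                    n_timepoints = 1000, seed = 1,
                                    radius = 60, box = 100,
                                    corr_kind = "block", rho = 0.6,
                                    block_size = 4) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- synth_structural(n_regions, radius = radius, box = box, seed = seed)
  corr <- synth_correlation(n_regions, corr_kind, rho, block_size)
  ts <- synth_gaussian_timeseries(corr, n_timepoints, seed = seed + 1,
                                  region_ids = sc$region_ids)
  nets <- rep(network_labels(), length.out = n_regions)
  parc <- tibble(region = sc$region_ids, network = nets,
                 hemisphere = rep(c("L", "R"), length.out = n_regions))
  paths <- c(
    sc = file.path(out_dir, "sc.tsv"),
    ts = file.path(out_dir, "ts.tsv"),
    atlas = file.path(out_dir, "atlas.tsv")
  )
  write_matrix(sc, paths[["sc"]])
  write_matrix(ts, paths[["ts"]], header = FALSE)
  write_tibble_tsv(parc, paths[["atlas"]])
  invisible(paths)
}
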