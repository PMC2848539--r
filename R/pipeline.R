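#' Parse a two-chain complex list
#'
#' Reads the 6-character entries used to enumerate the benchmark set: a
#' 4-character PDB code followed by the identifiers of the two interacting
#' chains (e.g. "1acbEI" = complex 1acb, chains E and I). One entry per
#' whitespace-separated token; duplicates are rejected.
#'
#' @param path text file of entries.
#' @return data.frame with columns `entry`, `pdb_code`, `chain_a`,
#'   `chain_b`; attribute `n_chains` gives the chain-sequence count
#'   (2 per complex).
#' @examples
#' f <- system.file("extdata", "dockground329.txt", package = "ifacecov")
#' nrow(load_complex_list(f))  # 329
#' @export
load_complex_list <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE)
  bad <- which(!grepl("^[0-9A-Za-z]{4}[A-Za-z0-9]{2}$", toks))
  if (length(bad) > 0L)
    stop("malformed entry '", toks[bad[1]], "' (token ", bad[1], ")",
         call. = FALSE)
  if (anyDuplicated(toks))
    stop("duplicate entries: ",
         paste(unique(toks[duplicated(toks)]), collapse = ", "),
         call. = FALSE)
  out <- data.frame(entry = toks,
                    pdb_code = substring(toks, 1, 4),
                    chain_a = substring(toks, 5, 5),
                    chain_b = substring(toks, 6, 6),
                    stringsAsFactors = FALSE)
  attr(out, "n_chains") <- 2L * nrow(out)
  out
}

#' Packaged reference tables
#'
#' `dockground_complexes()` returns the packaged list of 329 two-chain
#' complexes; `top_model_table()` returns the packaged table of partial
#' models built from full-interface-coverage alignments at 40% maximum
#' target coverage (26 top models plus 2 alternate best models), with their
#' printed alignment statistics and interface RMSD values.
#'
#' @return see above; `top_model_table()` is a data.frame with a `row_type`
#'   column ("top" or "best").
#' @export
dockground_complexes <- function() {
  load_complex_list(system.file("extdata", "dockground329.txt",
                                package = "ifacecov", mustWork = TRUE))
}

#' @rdname dockground_complexes
#' @export
top_model_table <- function() {
  utils::read.delim(system.file("extdata", "top_models_qmax40.tsv",
                                package = "ifacecov", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Bundles every knob of the analysis. Structures are given as a named
#' character vector of PDB paths (names = complex ids) with a parallel
#' vector of two-character chain selections.
#'
#' @param structures named character vector of PDB file paths.
#' @param chain_pairs named character vector like c(SYN1 = "AB").
#' @param alignments path to an alignment TSV (exchange format; rows must
#'   carry `complex_id` and `chain` matching the structures).
#' @param out_dir output directory (created if absent).
#' @param water_diameter,fic_tolerance,q_max,bin_width,fit_degree,matrix
#'   analysis parameters; see the respective functions.
#' @param domains optional named list of domain position vectors by
#'   target_id.
#' @param class_labels optional named character vector: functional class by
#'   complex id.
#' @param seed RNG seed recorded in the report.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(structures, chain_pairs, alignments, out_dir,
                            water_diameter = 2.8, fic_tolerance = 1L,
                            q_max = c(40, 50, 60, 70, 80, 90, 100),
                            bin_width = 5, fit_degree = 3L,
                            matrix = "BLOSUM62", domains = NULL,
                            class_labels = NULL, seed = 1L) {
  for (p in c(structures, alignments))
    if (!file.exists(p)) stop("input path does not exist: ", p,
                              call. = FALSE)
  if (water_diameter < 0 || fic_tolerance < 0 || bin_width <= 0 ||
      any(q_max <= 0 | q_max > 100))
    stop("numeric parameter out of range", call. = FALSE)
  structure(list(structures = structures, chain_pairs = chain_pairs,
                 alignments = alignments, out_dir = out_dir,
                 water_diameter = water_diameter,
                 fic_tolerance = as.integer(fic_tolerance), q_max = q_max,
                 bin_width = bin_width, fit_degree = as.integer(fit_degree),
                 matrix = matrix, domains = domains,
                 class_labels = class_labels, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full interface-coverage analysis
#'
#' Stages: read structures and assign interfaces; read the alignment pool;
#' apply the e-value and near-identical filters; compute per-alignment
#' metrics; build histograms, the FIC probability curves (identity and
#' similarity) with polynomial fits, per-complex FIC counts and q_max
#' subgroup counts. All intermediate tables are written as TSV under
#' `out_dir` and a JSON report summarises counts and configuration.
#'
#' @param config a [pipeline_config()].
#' @return the report, invisibly (also written to `out_dir/report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  vdw <- vdw_table(water_diameter = config$water_diameter)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))

  interfaces <- stage("interface", {
    out <- list()
    for (cid in names(config$structures)) {
      cx <- read_pdb(config$structures[[cid]], config$chain_pairs[[cid]],
                     id = cid)
      imap <- assign_interface(cx, vdw)
      write_interface_tsv(imap, file.path(config$out_dir,
                                          paste0("interface_", cid, ".tsv")))
      out[[cid]] <- list(structure = cx, interface = imap)
    }
    out
  })
  iface_positions <- list()
  for (cid in names(interfaces)) {
    cx <- interfaces[[cid]]$structure
    for (ch in names(cx$chains))
      iface_positions[[paste0(cid, ch)]] <-
        interface_positions(interfaces[[cid]]$interface, cx, ch)
  }

  pool <- stage("alignments", {
    p <- read_alignment_tsv(config$alignments)
    for (i in seq_len(nrow(p)))
      tryCatch(validate_alignment(pool_row(p, i)),
               error = function(e) stop("record ", i, ": ",
                                        conditionMessage(e), call. = FALSE))
    p
  })
  filt <- stage("filter", filter_pool(pool))
  report <- list(
    config = config[setdiff(names(config), c("domains", "class_labels"))],
    version = as.character(utils::packageVersion("ifacecov")),
    pool_size_input = nrow(pool),
    pool_size_kept = nrow(filt$kept),
    excluded = as.list(table(filt$excluded$reason)))

  if (nrow(filt$kept) > 0L) {
    metrics <- stage("metrics", compute_alignment_metrics(
      filt$kept, interfaces = iface_positions,
      matrix = substitution_matrix(config$matrix),
      fic_tolerance = config$fic_tolerance, domains = config$domains))
    utils::write.table(metrics, file.path(config$out_dir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$n_fic <- sum(metrics$is_fic)
    report$fic_fraction <- mean(metrics$is_fic)

    stage("stats", {
      for (m in c("a_iden", "a_sim", "i_iden", "i_sim")) {
        h <- metric_histogram(metrics, m, config$bin_width)
        utils::write.table(h, file.path(config$out_dir,
                                        paste0("hist_", m, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      fits <- list()
      for (m in c("a_iden", "a_sim")) {
        curve <- fic_probability(metrics, m, config$bin_width)
        utils::write.table(curve,
                           file.path(config$out_dir,
                                     paste0("fic_curve_", m, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        fits[[m]] <- tryCatch(
          fit_fic_curve(curve, config$fit_degree)[
            c("coefficients", "degree", "rss", "n_bins")],
          error = function(e) list(error = conditionMessage(e)))
      }
      jsonlite::write_json(fits, file.path(config$out_dir,
                                           "fic_fit.json"),
                           auto_unbox = TRUE, digits = NA)
      report$fic_fits <- fits
      counts <- count_fic_by_complex(
        metrics,
        complexes = do.call(rbind, lapply(names(interfaces), function(cid)
          data.frame(complex_id = cid,
                     chain = names(interfaces[[cid]]$structure$chains)))),
        class_labels = config$class_labels)
      utils::write.table(counts$totals,
                         file.path(config$out_dir, "fic_by_complex.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$fic_by_complex <- list(both = sum(counts$summaries$fic_both),
                                    one = sum(counts$summaries$fic_one),
                                    none = sum(counts$summaries$fic_none))
      report$qmax_counts <- lapply(stats::setNames(config$q_max,
                                                   config$q_max),
        function(qm) {
          sub <- metrics[metrics$q <= qm, , drop = FALSE]
          list(n_all = nrow(sub), n_fic = sum(sub$is_fic))
        })
    })
  } else {
    report$n_fic <- 0L
    report$fic_fraction <- NA
  }
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
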