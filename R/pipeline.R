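#' Configuration for an end-to-end analysis run
#'
#' @param input one input source per genotype: a [cohort()], a
#'   [sim_config()], or a path to a focus table readable by
#'   [read_focus_table()]; or an unnamed list of such sources for a
#'   multi-genotype comparison.
#' @param analyses subset of `c("gamma", "coc", "e_dist", "morphometry",
#'   "regression")`.
#' @param groups named list of bivalent-rank groups for the CoC curves;
#'   the default follows the usual long-versus-short presentation
#'   (bivalents 1–2 and 3–7, ranks by axis length).
#' @param units units for the gamma fit (see [fit_gamma_shape()]).
#' @param n_intervals interval rule for [coc_curve()].
#' @param n_bootstrap bootstrap resamples for the gamma shape SE.
#' @param seed integer seed recorded in every output and used for all
#'   stochastic stages.
#' @param out_dir optional directory; when set, [run_pipeline()] writes the
#'   result tables (CSV) and a manifest (JSON) there.
#' @return object of class `"run_config"`.
#' @export
run_config <- function(input,
                       analyses = c("gamma", "coc", "e_dist", "morphometry",
                                    "regression"),
                       groups = list("1-2" = 1:2, "3-7" = 3:7),
                       units = c("um", "percent"), n_intervals = "auto",
                       n_bootstrap = 200L, seed = 1L, out_dir = NULL) {
  units <- match.arg(units)
  analyses <- match.arg(analyses, several.ok = TRUE)
  sources <- if (inherits(input, c("cohort", "sim_config")) ||
                 is.character(input)) list(input) else input
  if (!length(sources)) stop("run_config needs at least one input source")
  structure(list(sources = sources, analyses = analyses, groups = groups,
                 units = units, n_intervals = n_intervals,
                 n_bootstrap = as.integer(n_bootstrap),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

resolve_source <- function(src, seed = NULL) {
  if (inherits(src, "cohort")) return(src)
  if (inherits(src, "sim_config")) return(simulate_cohort(src))
  if (is.character(src) && length(src) == 1L) return(read_focus_table(src))
  stop("input source must be a cohort, sim_config or file path")
}

# 32-bit FNV-1a over the deparsed config, for the manifest
fnv1a <- function(txt) {
  bytes <- utf8ToInt(paste(txt, collapse = "\n")) %% 256
  h <- 2166136261
  for (b in bytes) h <- (xor32(h, b) * 16777619) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full interference / morphometry analysis
#'
#' Composes the package end to end: resolve each input source to a cohort
#' (simulating when given a [sim_config()]), then per genotype fit the
#' gamma shape to pooled spacings, build CoC curves per bivalent group with
#' their interference distances, tabulate the focus-count E-distribution,
#' the morphometry summaries and the count-versus-length regression.
#' Identical configuration and seed give byte-identical numeric outputs.
#' Dropped data (zero spacings, skipped CoC pairs, cross-gap focus pairs)
#' are counted in the result objects rather than silently discarded.
#'
#' @param config a [run_config()].
#' @return object of class `"coc_report"`: per-genotype results under
#'   `$genotypes`, plus `$manifest` (package version, seed, config hash).
#' @examples
#' cfg <- run_config(sim_config(n_nuclei = 40, seed = 7), n_bootstrap = 20)
#' report <- run_pipeline(cfg)
#' report
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohorts <- lapply(config$sources, function(src)
    tryCatch(resolve_source(src, config$seed),
             error = function(e) stop("input stage failed: ",
                                      conditionMessage(e), call. = FALSE)))
  names(cohorts) <- vapply(cohorts, `[[`, character(1L), "genotype")

  analyse <- function(coh) {
    out <- list(genotype = coh$genotype, n_nuclei = length(coh$nuclei))
    stage <- function(name, expr) tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed for genotype '%s': %s",
                   name, coh$genotype, conditionMessage(e)), call. = FALSE))
    if ("gamma" %in% config$analyses)
      out$gamma_fit <- stage("gamma", {
        d <- pooled_distances(coh, units = config$units)
        fit_gamma_shape(d, n_bootstrap = config$n_bootstrap,
                        seed = config$seed, units = config$units)
      })
    if ("coc" %in% config$analyses)
      out$coc <- stage("coc", lapply(setNames(nm = names(config$groups)),
        function(g) coc_curve(coh, n_intervals = config$n_intervals,
                              ranks = config$groups[[g]], group = g)))
    if ("e_dist" %in% config$analyses)
      out$e_distribution <- stage("e_dist", e_distribution(coh))
    if ("morphometry" %in% config$analyses)
      out$morphometry <- stage("morphometry", {
        qs <- c("focus_count", "total_sc_length", "n_segments",
                "mean_inter_focus_distance")
        s <- lapply(setNames(nm = qs), function(q) summarize_cohort(coh, q))
        s$co_density <- co_density(coh)
        s
      })
    if ("regression" %in% config$analyses && length(coh$nuclei) >= 3L)
      out$regression <- stage("regression", regress_count_on_length(coh))
    out
  }

  report <- structure(
    list(genotypes = lapply(cohorts, analyse),
         manifest = list(package = "cocount",
                         version = as.character(utils::packageVersion("cocount")),
                         seed = config$seed,
                         config_hash = fnv1a(deparse(unclass(
                           config[setdiff(names(config), "out_dir")]))),
                         analyses = config$analyses,
                         units = config$units)),
    class = "coc_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, config$out_dir)
  }
  report
}

write_report <- function(report, out_dir) {
  for (g in names(report$genotypes)) {
    res <- report$genotypes[[g]]
    pre <- file.path(out_dir, gsub("[^A-Za-z0-9_.-]", "_", g))
    if (!is.null(res$gamma_fit))
      write_results(res$gamma_fit, paste0(pre, "_gamma.csv"))
    if (!is.null(res$coc))
      for (grp in names(res$coc))
        write_results(res$coc[[grp]],
                      paste0(pre, "_coc_", gsub("[^A-Za-z0-9_.-]", "_", grp),
                             ".csv"))
    if (!is.null(res$e_distribution))
      write_results(res$e_distribution, paste0(pre, "_edist.csv"))
    if (!is.null(res$morphometry)) {
      tab <- do.call(rbind, lapply(res$morphometry, as.data.frame))
      write_results(tab, paste0(pre, "_morphometry.csv"))
    }
    if (!is.null(res$regression))
      write_results(res$regression, paste0(pre, "_regression.csv"))
  }
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.coc_report <- function(x, ...) {
  cat(sprintf("<coc_report> %d genotype(s); seed %d, config %s\n",
              length(x$genotypes), x$manifest$seed, x$manifest$config_hash))
  for (res in x$genotypes) {
    cat(sprintf("-- %s (%d nuclei) --\n", res$genotype, res$n_nuclei))
    if (!is.null(res$gamma_fit)) print(res$gamma_fit)
    if (!is.null(res$coc)) for (cc in res$coc)
      cat(sprintf("  CoC group %-4s: interference distance %s\n", cc$group,
                  if (is.na(cc$interference_distance)) "not reached"
                  else sprintf("%.3f um", cc$interference_distance)))
    if (!is.null(res$morphometry)) {
      fc <- res$morphometry$focus_count
      sc <- res$morphometry$total_sc_length
      cat(sprintf("  foci/nucleus %.2f +/- %.2f; SC total %.2f +/- %.2f um\n",
                  fc$mean, fc$sd, sc$mean, sc$sd))
    }
    if (!is.null(res$regression))
      cat(sprintf("  foci ~ length: slope %.4f, R^2 %.4f\n",
                  res$regression$slope, res$regression$r_squared))
  }
  invisible(x)
}
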