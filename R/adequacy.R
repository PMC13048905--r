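# Parametric-bootstrap model adequacy.
#
# A fitted (tree, model) pair is used to simulate N replicate alignments;
# the observed value of a compositional statistic (mean per-site amino
# acid diversity "DIV", or maximum squared compositional deviation "MAX")
# is compared against the simulated null through a Z-score.  A model is
# deemed adequate for the statistic when -2 < Z < 2.

adequacy_statistic <- function(name) {
  switch(name,
         DIV = diversity_statistic,
         MAX = max_composition_deviation,
         stop("unknown statistic: ", name))
}

#' Parametric-bootstrap adequacy test
#'
#' @param aln observed alignment.
#' @param tree fitted tree (branch lengths required).
#' @param model fitted `rs_mixture` or `rs_pmsf`.
#' @param statistic `"DIV"` or `"MAX"`.
#' @param N number of simulated replicates (default 100).
#' @param seed integer seed.
#' @param model_tag label stored in the result (defaults to the model name).
#' @return an `rs_adequacy` list: `statistic`, `observed`, `simulated`,
#'   `mean_sim`, `sd_sim`, `z`, `adequate` (`-2 < z < 2`), `model_tag`,
#'   `N`, `seed`.
#' @export
parametric_bootstrap_test <- function(aln, tree, model,
                                      statistic = c("DIV", "MAX"),
                                      N = 100, seed = 1,
                                      model_tag = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(N >= 2)
  statfun <- adequacy_statistic(statistic)
  obs <- statfun(aln)
  reps <- parametric_replicates(tree, model, n_sites(aln), N, seed)
  sims <- vapply(reps, statfun, 0)
  sdv <- stats::sd(sims)
  if (sdv == 0) stop("zero simulated variance: Z undefined")
  z <- (obs - mean(sims)) / sdv
  structure(list(statistic = statistic, observed = obs, simulated = sims,
                 mean_sim = mean(sims), sd_sim = sdv, z = z,
                 adequate = z > -2 && z < 2,
                 model_tag = if (is.null(model_tag)) model$name else model_tag,
                 N = N, seed = seed), class = "rs_adequacy")
}

#' @export
print.rs_adequacy <- function(x, ...) {
  cat(sprintf("%s adequacy [%s]: observed %.4f, simulated %.4f +- %.4f, Z = %.2f (%s)\n",
              x$statistic, x$model_tag, x$observed, x$mean_sim, x$sd_sim,
              x$z, if (x$adequate) "adequate" else "inadequate"))
  invisible(x)
}

#' Rank adequacy results by absolute Z-score
#'
#' All results must concern the same observed data and statistic; the table
#' is sorted by `|Z|` ascending and flags the adequate set.
#'
#' @param results list of `rs_adequacy` objects.
#' @return data.frame: model_tag, z, abs_z, adequate.
#' @export
compare_adequacy <- function(results) {
  stopifnot(length(results) >= 1)
  stat <- unique(vapply(results, function(r) r$statistic, ""))
  if (length(stat) != 1) stop("mismatched statistics")
  obs <- vapply(results, function(r) r$observed, 0)
  if (length(results) > 1 && max(abs(diff(obs))) > 1e-9)
    stop("results concern different observed data")
  tab <- data.frame(model_tag = vapply(results, function(r) r$model_tag, ""),
                    z = vapply(results, function(r) r$z, 0),
                    stringsAsFactors = FALSE)
  tab$abs_z <- abs(tab$z)
  tab$adequate <- tab$z > -2 & tab$z < 2
  tab[order(tab$abs_z), ]
}

#' Export an adequacy result
#'
#' Writes a JSON summary and a TSV of the simulated statistic values.
#'
#' @param result an `rs_adequacy`.
#' @param json_path,tsv_path output files (either may be NULL to skip).
#' @export
write_adequacy <- function(result, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    out <- result[c("statistic", "observed", "mean_sim", "sd_sim", "z",
                    "adequate", "model_tag", "N", "seed")]
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_path))
    write.table(data.frame(sim = result$simulated), tsv_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(result)
}
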