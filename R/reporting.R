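#' Posterior density plot
#'
#' Writes a PNG with the kernel density (Silverman rule-of-thumb
#' bandwidth) of the pooled draws of one monitored quantity, with the
#' area under the density filled. Probability-scale quantities are drawn
#' on a (0, 1) x-axis. Constant draws degrade gracefully to a vertical
#' spike with a warning.
#'
#' @param draws an `hsroc_draws` object.
#' @param quantity monitored-quantity label, default `"other_snsp[max]"`.
#' @param path output PNG path.
#' @param title,xlab optional text; sensible defaults are derived from
#'   `quantity`.
#' @param width,height,res PNG device geometry (pixels / ppi).
#' @return `path`, invisibly.
#' @export
density_plot <- function(draws, quantity = "other_snsp[max]", path,
                         title = NULL, xlab = NULL,
                         width = 900, height = 600, res = 120) {
  x <- as.numeric(draws_matrix(draws, quantity))
  if (length(x) < 100L)
    stop("at least 100 draws are required for a density plot",
         call. = FALSE)
  prob_scale <- all(x >= 0 & x <= 1)
  if (is.null(title)) title <- paste("Posterior density of", quantity)
  if (is.null(xlab)) xlab <- if (prob_scale) "prob" else quantity
  open_png(path, width, height, res)
  on.exit(grDevices.dev_off())
  if (stats::sd(x) == 0) {
    warning("all draws of '", quantity,
            "' are identical; plotting a spike", call. = FALSE)
    xlim <- if (prob_scale) c(0, 1) else x[1] + c(-1, 1)
    graphics::plot(c(x[1], x[1]), c(0, 1), type = "l", lwd = 3,
                   col = "steelblue", xlim = xlim, xlab = xlab,
                   ylab = "density", main = title)
  } else {
    dn <- stats::density(x, bw = "nrd0")
    xlim <- if (prob_scale) c(0, 1) else range(dn$x)
    graphics::plot(dn, xlim = xlim, xlab = xlab, ylab = "density",
                   main = title, lwd = 2, col = "steelblue")
    graphics::polygon(c(dn$x, rev(dn$x)),
                      c(dn$y, rep(0, length(dn$y))),
                      col = grDevices::adjustcolor("steelblue", 0.4),
                      border = NA)
  }
  invisible(path)
}

#' Markov chain trace plot
#'
#' Writes a PNG with one line per chain over the retained (post-warmup,
#' thinned) iterations of one monitored quantity, with a chain legend —
#' the visual convergence check that complements [check_convergence()].
#'
#' @inheritParams density_plot
#' @param ylab y-axis label; defaults to `quantity`.
#' @return `path`, invisibly.
#' @export
trace_plot <- function(draws, quantity = "other_snsp[max]", path,
                       title = NULL, ylab = NULL,
                       width = 900, height = 600, res = 120) {
  m <- draws_matrix(draws, quantity)  # draws x chains
  if (ncol(m) < 2L) stop("at least 2 chains are required", call. = FALSE)
  if (is.null(title)) title <- paste("Trace of", quantity)
  if (is.null(ylab)) ylab <- quantity
  cols <- grDevices::hcl.colors(ncol(m), "Dark 3")
  open_png(path, width, height, res)
  on.exit(grDevices.dev_off())
  graphics::matplot(seq_len(nrow(m)), m, type = "l", lty = 1,
                    col = cols, xlab = "post-warmup iteration",
                    ylab = ylab, main = title)
  graphics::legend("topright", legend = paste("chain", seq_len(ncol(m))),
                   col = cols, lty = 1, cex = 0.8, bg = "white")
  invisible(path)
}

# Prefer a cairo PNG device (works headless); fall back to the default.
open_png <- function(path, width, height, res) {
  ok <- tryCatch({
    grDevices::png(path, width = width, height = height, res = res,
                   type = "cairo")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) grDevices::png(path, width = width, height = height, res = res)
  invisible(NULL)
}

grDevices.dev_off <- function() {
  if (grDevices::dev.cur() > 1) grDevices::dev.off()
}

#' Export the MCMC summary table as CSV
#'
#' Writes [summarize_draws()] output with the conventional column
#' headers `Statistics, Mean, se_mean, sd, X2.5., X25., X50., X75.,
#' X97.5., n_eff, Rhat`. Values are written at full precision and
#' round-trip through [utils::read.csv()] unchanged.
#'
#' @param t an [summarize_draws()] table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_mcmc_csv <- function(t, path) {
  if (!is.data.frame(t) || nrow(t) == 0L)
    stop("the summary table is empty", call. = FALSE)
  out <- data.frame(Statistics = t$name, Mean = t$mean,
                    se_mean = t$se_mean, sd = t$sd,
                    X2.5. = t$q2.5, X25. = t$q25, X50. = t$q50,
                    X75. = t$q75, X97.5. = t$q97.5,
                    n_eff = t$n_eff, Rhat = t$rhat,
                    check.names = FALSE)
  utils::write.csv(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summary-of-findings row
#'
#' Renders the quantitative row of a GRADE-style summary-of-findings
#' table for diagnostic accuracy: the fixed measure and its value, the
#' estimated measure with its 95% credible interval, and — when a
#' prevalence is supplied — the expected numbers of true/false
#' positives/negatives per `n_per_1000` patients. Certainty-of-evidence
#' judgments are human work and are not generated.
#'
#' @param sp an [summary_point()] result.
#' @param target the matching [fixed_target()].
#' @param n_per_1000 cohort size for the absolute numbers (default 1000).
#' @param prevalence assumed disease prevalence in (0, 1), or `NULL` to
#'   omit the absolute-numbers lines.
#' @return A character vector of text lines.
#' @export
#' @examples
#' tg <- fixed_target("specificity", 0.8)
#' sp <- structure(list(measure = "sensitivity", estimate = 0.77,
#'                      cri_low = 0.64, cri_high = 0.90,
#'                      fixed_measure = "specificity", fixed_value = 0.8),
#'                 class = "hsroc_summary_point")
#' cat(sof_row(sp, tg, prevalence = 0.30), sep = "\n")
sof_row <- function(sp, target, n_per_1000 = 1000, prevalence = NULL) {
  if (!inherits(sp, "hsroc_summary_point"))
    stop("sp must be a summary_point() result", call. = FALSE)
  if (!is.null(prevalence) &&
      (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1))
    stop("prevalence must be strictly inside (0, 1)", call. = FALSE)
  lines <- c(
    sprintf("Fixed %s: %.3f", sp$fixed_measure, sp$fixed_value),
    sprintf("Estimated %s: %.3f (95%% CrI %.3f to %.3f)", sp$measure,
            sp$estimate, sp$cri_low, sp$cri_high))
  if (!is.null(prevalence)) {
    sens <- if (sp$measure == "sensitivity") sp$estimate else
      sp$fixed_value
    spec <- if (sp$measure == "specificity") sp$estimate else
      sp$fixed_value
    nd <- n_per_1000 * prevalence
    nn <- n_per_1000 * (1 - prevalence)
    lines <- c(lines, sprintf(
      paste0("Per %d patients at prevalence %.2f: ",
             "TP %d, FN %d, TN %d, FP %d"),
      n_per_1000, prevalence,
      round(nd * sens), round(nd * (1 - sens)),
      round(nn * spec), round(nn * (1 - spec))))
  }
  lines
}
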