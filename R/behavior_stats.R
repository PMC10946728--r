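# Behavioural pipeline: RT outlier filtering, outcome/RT tables, two-way
# repeated-measures ANOVA and paired t-tests.

#' Filter response-time outliers
#'
#' Within each participant x condition cell, removes (in a single pass)
#' trials whose RT deviates from the cell mean by more than `k` standard
#' deviations. The default cell definition is participant x outcome class
#' (TP/TN/FP/FN); `cells = "rate_class"` switches to participant x
#' (probe rate x trial class).
#'
#' @param table Behaviour data frame with columns `rt_ms`, `outcome`,
#'   `probe_rate`, `class`, and optionally `participant_id`.
#' @param k SD multiplier (study value 2.5).
#' @param cells `"outcome"` (default) or `"rate_class"`.
#' @return The filtered data frame.
#' @export
filter_rt_outliers <- function(table, k = 2.5, cells = c("outcome", "rate_class")) {
  cells <- match.arg(cells)
  pid <- if ("participant_id" %in% names(table)) table$participant_id else "P"
  cell <- if (cells == "outcome") {
    paste(pid, table$outcome)
  } else {
    paste(pid, table$probe_rate, table$class)
  }
  keep <- rep(TRUE, nrow(table))
  for (g in split(seq_len(nrow(table)), cell)) {
    if (length(g) < 2) next
    rt <- table$rt_ms[g]
    s <- stats::sd(rt)
    if (!is.finite(s) || s == 0) next
    out <- abs(rt - mean(rt)) > k * s
    keep[g[out]] <- FALSE
    if (all(out)) warning("a participant x condition cell became empty")
  }
  table[keep, , drop = FALSE]
}

#' Per-participant outcome percentages and mean RTs
#'
#' Outcome percentages are computed within trial class so that, for each
#' probe rate, %TP + %FN = 100 (same trials) and %TN + %FP = 100 (different
#' trials). Mean RTs are reported per outcome x rate cell.
#'
#' @param table Behaviour data frame (columns `participant_id`, `class`,
#'   `probe_rate`, `outcome`, `rt_ms`).
#' @return Data frame: participant_id, probe_rate, outcome, pct, mean_rt_ms.
#' @export
outcome_table <- function(table) {
  if (!nrow(table)) stop("empty behaviour table")
  if (!"participant_id" %in% names(table)) table$participant_id <- "P"
  outcomes <- c("TP", "FN", "TN", "FP")
  cls <- c(TP = "same", FN = "same", TN = "different", FP = "different")
  grid <- expand.grid(participant_id = unique(table$participant_id),
                      probe_rate = sort(unique(table$probe_rate)),
                      outcome = outcomes, stringsAsFactors = FALSE)
  grid$pct <- NA_real_
  grid$mean_rt_ms <- NA_real_
  for (i in seq_len(nrow(grid))) {
    base <- table$participant_id == grid$participant_id[i] &
      table$probe_rate == grid$probe_rate[i] &
      table$class == cls[[grid$outcome[i]]]
    hit <- base & table$outcome == grid$outcome[i]
    grid$pct[i] <- if (any(base)) 100 * sum(hit) / sum(base) else NA_real_
    grid$mean_rt_ms[i] <- if (any(hit)) mean(table$rt_ms[hit]) else NA_real_
  }
  grid
}

#' Two-way repeated-measures ANOVA
#'
#' Classical within-subject ANOVA on a complete, balanced participants x A x
#' B cube of cell means: each effect is tested against its subject x effect
#' interaction error term (fit via `aov` with an `Error(subject/(A*B))`
#' stratum); no sphericity correction is applied. For a 23-participant
#' 4 x 3 design the dfs are (3, 66), (2, 44) and (6, 132).
#'
#' @param cube Numeric array participants x levelsA x levelsB; dimnames on
#'   dimensions 2 and 3 are used as factor levels if present.
#' @param names_ab Names of the two factors (for the output table).
#' @return An `anova_result`: data frame `table` (effect, F, df1, df2, p)
#'   plus `cell_means`.
#' @export
rm_anova_2way <- function(cube, names_ab = c("A", "B")) {
  stopifnot(is.array(cube), length(dim(cube)) == 3)
  if (any(!is.finite(cube))) stop("missing cells; the design must be complete")
  d <- dim(cube)
  if (d[1] < 2) stop("need at least 2 participants")
  la <- dimnames(cube)[[2]]; if (is.null(la)) la <- paste0("a", seq_len(d[2]))
  lb <- dimnames(cube)[[3]]; if (is.null(lb)) lb <- paste0("b", seq_len(d[3]))
  df <- data.frame(
    y = as.vector(cube),
    subject = factor(rep(seq_len(d[1]), d[2] * d[3])),
    A = factor(rep(rep(la, each = d[1]), d[3]), levels = la),
    B = factor(rep(lb, each = d[1] * d[2]), levels = lb)
  )
  fit <- stats::aov(y ~ A * B + Error(subject / (A * B)), data = df)
  s <- summary(fit)
  pull <- function(stratum, term) {
    tab <- s[[stratum]][[1]]
    i <- match(term, trimws(rownames(tab)))
    c(F = tab[i, "F value"], df1 = tab[i, "Df"],
      df2 = tab[nrow(tab), "Df"], p = tab[i, "Pr(>F)"])
  }
  eff <- rbind(pull("Error: subject:A", "A"),
               pull("Error: subject:B", "B"),
               pull("Error: subject:A:B", "A:B"))
  tab <- data.frame(
    effect = c(names_ab[1], names_ab[2], paste(names_ab, collapse = ":")),
    F = eff[, "F"], df1 = eff[, "df1"], df2 = eff[, "df2"], p = eff[, "p"]
  )
  tab$p[!is.finite(tab$p)] <- 0   # guard for degenerate noiseless designs
  cm <- apply(cube, c(2, 3), mean)
  dimnames(cm) <- list(la, lb)
  structure(list(table = tab, cell_means = cm, n_participants = d[1]),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (%d participants)\n", x$n_participants))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-12s F(%d, %d) = %.2f, p = %.4g\n", tab$effect[i],
                tab$df1[i], tab$df2[i], tab$F[i], tab$p[i]))
  }
  invisible(x)
}

#' Paired two-sided t-test
#'
#' @param x,y Equal-length numeric vectors (n >= 2), paired by position.
#' @return List with `t`, `df`, `p`. Zero-variance differences yield a
#'   signed infinite t with p = 0 (or t = 0, p = 1 when x == y).
#' @export
paired_t_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, df = length(d) - 1, p = 1))
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1, p = 0))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Behavioural ANOVAs and follow-up contrasts for a study
#'
#' Runs the RT outlier filter, builds the per-participant outcome x rate
#' tables, and computes the two repeated-measures ANOVAs (performance
#' percentages and mean RTs) plus the RT follow-up paired t-tests
#' (TP vs TN, TP vs FP, TN vs FN, pooled over rates).
#'
#' @param behavior Combined behaviour data frame for all participants.
#' @param rt_k RT outlier threshold (SDs).
#' @param cells RT-filter cell definition (see [filter_rt_outliers()]).
#' @return List: `table` (tidy cell statistics), `anova_pct`, `anova_rt`,
#'   `followup_rt` (data frame of contrasts).
#' @export
behavior_study_stats <- function(behavior, rt_k = 2.5, cells = "outcome") {
  filt <- filter_rt_outliers(behavior, k = rt_k, cells = cells)
  tab <- outcome_table(filt)
  pids <- unique(tab$participant_id)
  outcomes <- c("TP", "TN", "FP", "FN")
  rates <- sort(unique(tab$probe_rate))
  cube_pct <- array(NA_real_, c(length(pids), 4, length(rates)),
                    dimnames = list(NULL, outcomes, rates))
  cube_rt <- cube_pct
  for (i in seq_len(nrow(tab))) {
    p <- match(tab$participant_id[i], pids)
    o <- match(tab$outcome[i], outcomes)
    r <- match(tab$probe_rate[i], rates)
    cube_pct[p, o, r] <- tab$pct[i]
    cube_rt[p, o, r] <- tab$mean_rt_ms[i]
  }
  anova_pct <- rm_anova_2way(cube_pct, names_ab = c("outcome", "rate"))
  # RT cells can be empty by chance in small simulations; the within-subject
  # ANOVA needs a complete cube, so it is skipped (with a warning) when one is
  # missing rather than imputed.
  anova_rt <- if (all(is.finite(cube_rt))) {
    rm_anova_2way(cube_rt, names_ab = c("outcome", "rate"))
  } else {
    warning("empty outcome x rate RT cells; RT ANOVA skipped")
    NULL
  }
  # follow-up contrasts use trial-level per-outcome mean RTs (pooled over
  # rates), restricted to participants with all four outcomes observed
  rt_by_outcome <- matrix(NA_real_, length(pids), 4,
                          dimnames = list(pids, outcomes))
  agg <- stats::aggregate(rt_ms ~ participant_id + outcome, data = filt, mean)
  rt_by_outcome[cbind(match(agg$participant_id, pids),
                      match(agg$outcome, outcomes))] <- agg$rt_ms
  complete <- stats::complete.cases(rt_by_outcome)
  if (!all(complete))
    warning(sum(!complete), " participant(s) without all four outcomes ",
            "dropped from RT contrasts")
  rt_by_outcome <- rt_by_outcome[complete, , drop = FALSE]
  contrast <- function(a, b) {
    tt <- paired_t_test(rt_by_outcome[, a], rt_by_outcome[, b])
    data.frame(contrast = paste(a, "vs", b), t = tt$t, df = tt$df, p = tt$p,
               mean_diff = mean(rt_by_outcome[, a] - rt_by_outcome[, b]))
  }
  followup <- rbind(contrast("TP", "TN"), contrast("TP", "FP"),
                    contrast("TN", "FN"))
  list(table = tab, anova_pct = anova_pct, anova_rt = anova_rt,
       followup_rt = followup)
}
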