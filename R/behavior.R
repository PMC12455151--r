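#' Paired-t sample size for a planned within-subject contrast
#'
#' Standard a-priori power computation for a paired t test on a standardised
#' difference score d_z, as used to size cueing experiments: the smallest
#' integer n with power at least `power` at two-sided level `sig.level`.
#'
#' @param d standardised effect size d_z (mean difference / SD of
#'   differences).
#' @param power target power.
#' @param sig.level two-sided type-I level.
#' @return integer sample size (subjects).
#' @examples
#' paired_t_sample_size(1.01, 0.8, 0.05)  # 10
#' @export
paired_t_sample_size <- function(d, power = 0.8, sig.level = 0.05) {
  res <- stats::power.t.test(delta = d, sd = 1, power = power,
                             sig.level = sig.level, type = "paired")
  as.integer(ceiling(res$n))
}

#' Screen participants by overall accuracy
#'
#' Retains subjects whose overall accuracy across all trials exceeds the
#' cut-off (default 55%); the comparison is strict, so a subject exactly at
#' the cut-off is excluded.
#'
#' @param tables named list of per-subject trial tables (see
#'   [generate_trial_table()]).
#' @param cutoff accuracy threshold (proportion).
#' @return list with `retained` (subject names), `excluded`, and `log`
#'   (data.frame subject, accuracy, retained).
#' @export
screen_participants <- function(tables, cutoff = 0.55) {
  if (!length(tables)) stop("no subject tables supplied")
  if (is.null(names(tables))) names(tables) <- sprintf("S%02d", seq_along(tables))
  acc <- vapply(names(tables), function(s) {
    tab <- tables[[s]]
    if (!nrow(tab)) stop("subject ", s, " has an empty trial table")
    mean(tab$correct)
  }, numeric(1))
  keep <- acc > cutoff
  list(
    retained = names(tables)[keep],
    excluded = names(tables)[!keep],
    log = data.frame(subject = names(tables), accuracy = unname(acc),
                     retained = unname(keep))
  )
}

#' Filter trials for RT analysis
#'
#' Removes incorrect-response trials and trials with RTs faster than 100 ms
#' or slower than 2000 ms. Both bounds are strict ("faster/slower than"), so
#' RTs exactly at 100 or 2000 ms are kept.
#'
#' @param table a trial table with `correct` and `rt_ms` columns.
#' @param lower,upper RT bounds in ms.
#' @return the filtered table, with the removed fraction attached as
#'   attribute `removed_fraction`.
#' @export
filter_rts <- function(table, lower = 100, upper = 2000) {
  if (!"rt_ms" %in% names(table)) stop("`rt_ms` column required")
  keep <- table$correct == 1 & table$rt_ms >= lower & table$rt_ms <= upper
  out <- table[keep, , drop = FALSE]
  if (!nrow(out)) warning("no trials survive RT filtering")
  attr(out, "removed_fraction") <- 1 - nrow(out) / nrow(table)
  out
}

#' Signal-detection sensitivity d'
#'
#' d' = qnorm(hit rate) - qnorm(false-alarm rate). Extreme rates of 0 or 1
#' are replaced by 1/(2N) and 1 - 1/(2N), where N is the number of trials in
#' the corresponding class, so the z transform stays finite.
#'
#' @param hits,misses counts on signal trials.
#' @param fas,crs false alarms and correct rejections on noise trials.
#' @return d' (numeric scalar).
#' @examples
#' compute_dprime(90, 10, 10, 90)  # ~2.563
#' @export
compute_dprime <- function(hits, misses, fas, crs) {
  n_sig <- hits + misses
  n_noise <- fas + crs
  if (n_sig <= 0 || n_noise <= 0) {
    stop("need at least one signal trial and one noise trial")
  }
  hr <- clamp_rate(hits / n_sig, n_sig)
  far <- clamp_rate(fas / n_noise, n_noise)
  stats::qnorm(hr) - stats::qnorm(far)
}

clamp_rate <- function(r, n) {
  if (r <= 0) return(1 / (2 * n))
  if (r >= 1) return(1 - 1 / (2 * n))
  r
}

#' Per-subject condition x validity summary
#'
#' Computes d' (letter-as-signal convention: 'E' signal, 'H' noise), mean RT
#' over correct RT-filtered trials, accuracy, and the trial count used, for
#' every condition x validity cell of a subject's table.
#'
#' @param table one subject's trial table.
#' @return data.frame with one row per condition x validity cell.
#' @export
subject_summary <- function(table) {
  cells <- unique(table[c("condition", "validity")])
  cells <- cells[order(cells$condition, cells$validity), ]
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- table[table$condition == cells$condition[i] &
                   table$validity == cells$validity[i], ]
    hits <- sum(sub$target == "E" & sub$correct == 1)
    misses <- sum(sub$target == "E" & sub$correct == 0)
    fas <- sum(sub$target == "H" & sub$correct == 0)
    crs <- sum(sub$target == "H" & sub$correct == 1)
    rt_sub <- suppressWarnings(filter_rts(sub))
    data.frame(
      condition = cells$condition[i], validity = cells$validity[i],
      d_prime = compute_dprime(hits, misses, fas, crs),
      mean_rt = if (nrow(rt_sub)) mean(rt_sub$rt_ms) else NA_real_,
      accuracy = mean(sub$correct),
      n_trials_used = nrow(rt_sub)
    )
  })
  do.call(rbind, res)
}

#' Two-way repeated-measures ANOVA
#'
#' Classical within-subject sums-of-squares decomposition for a fully
#' crossed factorial design: each effect (factor A, factor B, their
#' interaction) is tested against its own effect x subject interaction as
#' the error term. Partial eta squared is SS_effect /
#' (SS_effect + SS_error). No sphericity correction is applied, so the
#' degrees of freedom follow the raw cell structure.
#'
#' @param data long data.frame with one row per subject x cell.
#' @param dv name of the dependent-variable column.
#' @param within names of the two within-subject factor columns (default
#'   `condition` and `validity`).
#' @param subject name of the subject id column.
#' @return data.frame with one row per effect: F, df_num, df_den, p,
#'   partial eta squared.
#' @export
rm_anova <- function(data, dv, within = c("condition", "validity"),
                     subject = "subject") {
  f1 <- factor(data[[within[1]]])
  f2 <- factor(data[[within[2]]])
  subj <- factor(data[[subject]])
  y <- data[[dv]]
  a <- nlevels(f1); b <- nlevels(f2); n <- nlevels(subj)
  if (n < 2) stop("need at least 2 subjects")
  counts <- table(subj, f1, f2)
  if (any(counts != 1)) {
    bad <- which(counts == 0, arr.ind = TRUE)
    if (nrow(bad)) {
      labs <- apply(bad, 1, function(r) {
        paste(dimnames(counts)[[1]][r[1]], dimnames(counts)[[2]][r[2]],
              dimnames(counts)[[3]][r[3]], sep = ":")
      })
      stop("missing cells: ", paste(labs, collapse = ", "))
    }
    stop("design must have exactly one observation per subject x cell")
  }
  gm <- mean(y)
  m_a <- tapply(y, f1, mean); m_b <- tapply(y, f2, mean)
  m_s <- tapply(y, subj, mean)
  m_ab <- tapply(y, list(f1, f2), mean)
  m_as <- tapply(y, list(f1, subj), mean)
  m_bs <- tapply(y, list(f2, subj), mean)

  ss_a <- b * n * sum((m_a - gm)^2)
  ss_b <- a * n * sum((m_b - gm)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, m_b, "+") + gm)^2)
  ss_as <- b * sum((m_as - outer(m_a, m_s, "+") + gm)^2)
  ss_bs <- a * sum((m_bs - outer(m_b, m_s, "+") + gm)^2)
  cell_mean <- m_ab[cbind(as.integer(f1), as.integer(f2))]
  resid <- y - cell_mean -
    m_as[cbind(as.integer(f1), as.integer(subj))] + m_a[as.integer(f1)] -
    m_bs[cbind(as.integer(f2), as.integer(subj))] + m_b[as.integer(f2)] +
    m_s[as.integer(subj)] - gm
  ss_abs <- sum(resid^2)

  eff <- function(name, ss_e, df_e, ss_err, df_err) {
    ms_e <- ss_e / df_e; ms_err <- ss_err / df_err
    F <- if (ss_err == 0 && ss_e == 0) 0 else ms_e / ms_err
    data.frame(effect = name, F = F, df_num = df_e, df_den = df_err,
               p = stats::pf(F, df_e, df_err, lower.tail = FALSE),
               pes = if (ss_e + ss_err > 0) ss_e / (ss_e + ss_err) else 0)
  }
  rbind(
    eff(within[1], ss_a, a - 1, ss_as, (a - 1) * (n - 1)),
    eff(within[2], ss_b, b - 1, ss_bs, (b - 1) * (n - 1)),
    eff(paste(within, collapse = ":"), ss_ab, (a - 1) * (b - 1),
        ss_abs, (a - 1) * (b - 1) * (n - 1))
  )
}

#' Planned paired contrast between two cells
#'
#' Paired two-sided t test on per-subject differences between two
#' condition x validity cells.
#'
#' @param data long data.frame (as for [rm_anova()]).
#' @param dv dependent-variable column name.
#' @param cellA,cellB named lists (or vectors) selecting the two cells, e.g.
#'   `list(condition = "high_uc", validity = "valid")`.
#' @param subject subject id column name.
#' @return list with `t`, `df`, `p`, `mean_diff`, `sd_diff`, `n`.
#' @export
paired_contrasts <- function(data, dv, cellA, cellB, subject = "subject") {
  pick <- function(cell) {
    keep <- rep(TRUE, nrow(data))
    for (f in names(cell)) keep <- keep & data[[f]] == cell[[f]]
    sub <- data[keep, ]
    stats::setNames(sub[[dv]], sub[[subject]])
  }
  xa <- pick(cellA); xb <- pick(cellB)
  common <- intersect(names(xa), names(xb))
  if (length(common) < length(unique(data[[subject]]))) {
    stop("both cells must be present for all subjects")
  }
  d <- xa[common] - xb[common]
  n <- length(d)
  if (n < 2) stop("need at least 2 subjects")
  md <- mean(d); sd_d <- stats::sd(d)
  if (sd_d == 0) {
    t <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
  } else {
    t <- md / (sd_d / sqrt(n))
    p <- 2 * stats::pt(-abs(t), n - 1)
  }
  list(t = t, df = n - 1, p = p, mean_diff = md, sd_diff = sd_d, n = n)
}
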