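## Two-way repeated-measures ANOVA with the simulation as the random unit.

## one- or two-way fully-within RM ANOVA from a long table with one
## observation per subject x cell; returns per-effect SS against its
## subject-interaction error term
rm_anova_table <- function(y, subj, A, B = NULL) {
  subj <- factor(subj); A <- factor(A)
  if (nlevels(subj) < 2L) {
    stop("repeated-measures analysis needs at least 2 simulations")
  }
  gm <- mean(y)
  m_s <- tapply(y, subj, mean); m_a <- tapply(y, A, mean)
  ns <- nlevels(subj); na <- nlevels(A)
  eff <- function(ss_eff, df_eff, ss_err, df_err, label) {
    ms_eff <- ss_eff / df_eff; ms_err <- ss_err / df_err
    f <- if (ss_eff < 1e-15 && ss_err < 1e-15) 0 else ms_eff / ms_err
    p <- if (f == 0 && ms_err == 0) 1 else stats::pf(f, df_eff, df_err,
                                                    lower.tail = FALSE)
    pes <- if (ss_eff + ss_err == 0) 0 else ss_eff / (ss_eff + ss_err)
    data.frame(effect = label, F = f, df1 = df_eff, df2 = df_err, p = p,
               pes = pes, stringsAsFactors = FALSE)
  }
  if (is.null(B)) {
    stopifnot(length(y) == ns * na)
    ss_a <- ns * sum((m_a - gm)^2)
    m_sa <- tapply(y, list(subj, A), mean)
    ss_sa <- sum((m_sa - outer(m_s, m_a, `+`) + gm)^2)
    return(eff(ss_a, na - 1, ss_sa, (na - 1) * (ns - 1), "A"))
  }
  B <- factor(B)
  nb <- nlevels(B)
  stopifnot(length(y) == ns * na * nb)
  m_b <- tapply(y, B, mean)
  m_ab <- tapply(y, list(A, B), mean)
  m_sa <- tapply(y, list(subj, A), mean)
  m_sb <- tapply(y, list(subj, B), mean)

  ss_a <- ns * nb * sum((m_a - gm)^2)
  ss_b <- ns * na * sum((m_b - gm)^2)
  ss_ab <- ns * sum((m_ab - outer(m_a, m_b, `+`) + gm)^2)
  ss_sa <- nb * sum((m_sa - outer(m_s, m_a, `+`) + gm)^2)
  ss_sb <- na * sum((m_sb - outer(m_s, m_b, `+`) + gm)^2)
  ## residual = SS_total - all other terms
  ss_s <- na * nb * sum((m_s - gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_sab <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_sa - ss_sb
  ss_sab <- max(ss_sab, 0)

  rbind(eff(ss_a, na - 1, ss_sa, (na - 1) * (ns - 1), "A"),
        eff(ss_b, nb - 1, ss_sb, (nb - 1) * (ns - 1), "B"),
        eff(ss_ab, (na - 1) * (nb - 1), ss_sab,
            (na - 1) * (nb - 1) * (ns - 1), "A:B"))
}

#' Repeated-measures interaction analysis of a lesion battery
#'
#' Two-way fully-within-simulation ANOVA of a condition-summary table
#' (factor A = lesion status, factor B = condition), with simple effects of
#' lesioning within each condition as follow-ups. p-values come from the F
#' distribution; with two-level factors no sphericity correction is needed.
#'
#' @param summaries Output of [summarize_battery()] (optionally filtered to a
#'   subset of conditions, e.g. typical vs atypical for the 2x2).
#' @param dv Dependent variable column (default `"accuracy"`).
#' @return List with `effects` (main effects and interaction: F, df, p,
#'   partial eta squared) and `simple_effects` (lesion effect within each
#'   condition).
#' @export
interaction_anova <- function(summaries, dv = "accuracy") {
  need <- c("simulation_seed", "condition", "lesion_status", dv)
  if (!all(need %in% names(summaries))) {
    stop("summary table lacks columns: ",
         paste(setdiff(need, names(summaries)), collapse = ", "))
  }
  tab <- table(summaries$simulation_seed, summaries$condition,
               summaries$lesion_status)
  if (any(tab != 1L)) {
    stop("unbalanced design: every simulation must contribute every ",
         "condition x lesion-status cell exactly once")
  }
  y <- summaries[[dv]]
  eff <- rm_anova_table(y, summaries$simulation_seed,
                        summaries$lesion_status, summaries$condition)
  eff$effect <- c("lesion", "condition", "lesion:condition")

  simple <- do.call(rbind, lapply(split(summaries, summaries$condition),
                                  function(d) {
    r <- rm_anova_table(d[[dv]], d$simulation_seed, d$lesion_status)
    r$effect <- paste0("lesion within ", d$condition[1])
    r
  }))
  rownames(simple) <- NULL
  list(effects = eff, simple_effects = simple, dv = dv)
}
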