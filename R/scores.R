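#' Stay-probability table of a session
#'
#' Cross-tabulates the probability of repeating the first-stage choice on
#' trial t+1 by the transition type and reward of trial t. Only consecutive
#' trial pairs within a block (and surviving any trial exclusions) count;
#' a cell with no pairs is `NA`.
#'
#' @param data single-session trial table.
#' @return A data frame with one row per transition x reward cell:
#'   `transition`, `reward`, `p_stay`, `n_pairs`.
#' @examples
#' d <- simulate_twostep(rl_params(0.5, 5, 0.6, 1, 0),
#'                       task_config(n_trials = 100), seed = 1)
#' stay_table(d)
#' @export
stay_table <- function(data) {
  ses <- session_vectors(data, need_rt = FALSE)
  pairs <- stay_pairs(data)
  grid <- expand.grid(transition = c("common", "rare"), reward = c(1L, 0L),
                      stringsAsFactors = FALSE)
  grid$p_stay <- NA_real_
  grid$n_pairs <- 0L
  for (i in seq_len(nrow(grid))) {
    sel <- pairs$transition == grid$transition[i] & pairs$reward == grid$reward[i]
    grid$n_pairs[i] <- sum(sel)
    if (any(sel)) grid$p_stay[i] <- mean(pairs$stay[sel])
  }
  grid
}

# consecutive (t, t+1) pairs within a block: conditioning trial's transition
# and reward, outcome trial's stay indicator and its trial index (for the
# odd/even split of the outcome trial)
stay_pairs <- function(data) {
  n <- nrow(data)
  if (n < 2) return(data.frame(transition = character(), reward = integer(),
                               stay = integer(), outcome_trial = integer()))
  i <- seq_len(n - 1)
  keep <- data$block[i + 1] == data$block[i] &
    data$trial[i + 1] == data$trial[i] + 1
  i <- i[keep]
  data.frame(transition = data$transition[i], reward = as.integer(data$reward[i]),
             stay = as.integer(data$choice1[i + 1] == data$choice1[i]),
             outcome_trial = data$trial[i + 1])
}

#' Choice-based model-basedness score (MB-I)
#'
#' The transition-by-reward interaction on stay probability:
#' `(P(stay | common, rewarded) - P(stay | rare, rewarded)) -
#'  (P(stay | common, unrewarded) - P(stay | rare, unrewarded))`.
#' Positive values indicate model-based control; a purely model-free agent
#' shows only a reward main effect and scores 0 in expectation.
#'
#' @param data single-session trial table.
#' @return Scalar score in \[-2, 2\], or `NA` if any cell is undefined.
#' @export
mb1_choice <- function(data) {
  tab <- stay_table(data)
  cell <- function(tr, r) tab$p_stay[tab$transition == tr & tab$reward == r]
  (cell("common", 1) - cell("rare", 1)) - (cell("common", 0) - cell("rare", 0))
}

#' RT-based model-basedness score (MB-II)
#'
#' Mean second-stage reaction time after rare transitions minus after common
#' transitions (the current trial's transition). Model-based agents
#' discriminate second-stage values better after common transitions, making
#' them faster there, so positive values indicate model-based control.
#'
#' @param data single-session trial table with `rt2_s`.
#' @return Scalar score in seconds, or `NA` if a transition type is absent.
#' @export
mb2_rt <- function(data) {
  if (!"rt2_s" %in% names(data) || all(is.na(data$rt2_s))) return(NA_real_)
  rare <- data$rt2_s[data$transition == "rare"]
  common <- data$rt2_s[data$transition == "common"]
  if (!length(rare) || !length(common)) return(NA_real_)
  mean(rare, na.rm = TRUE) - mean(common, na.rm = TRUE)
}

#' Model-agnostic scores for a cohort
#'
#' Computes per-subject, per-timepoint model-basedness scores. Individual
#' scores are the descriptive differences [mb1_choice()] and [mb2_rt()].
#' Hierarchical scores shrink towards the group via mixed-effects models
#' fitted across subjects within each timepoint: a mixed logistic regression
#' of stay on previous transition x reward (coded -1/+1, full factorial
#' fixed and random effects; the subject-level interaction slope is the
#' score) and a mixed linear regression of second-stage RT on transition
#' (random intercept and slope; the subject-level transition slope is the
#' score). Both hierarchical scores are signed so that positive = more
#' model-based.
#'
#' @param data multi-subject trial table.
#' @param hierarchical also compute mixed-model scores (requires >= 2
#'   subjects; needs the `lme4` package machinery, used with the BOBYQA
#'   optimizer).
#' @return A data frame with one row per subject x timepoint: stay cells,
#'   `mb1`, `mb2`, and (if requested) `mb1_h`, `mb2_h`.
#' @examples
#' p <- ddmrl_params(alpha1 = 0.5, lambda = 0.6, w = 1, p = 0.1,
#'                   b1 = 5, a1 = 2, tau1 = 0.3)
#' d <- simulate_twostep(p, task_config(n_trials = 100), n_subjects = 4, seed = 1)
#' twostep_scores(d)
#' @export
twostep_scores <- function(data, hierarchical = FALSE) {
  sessions <- split_sessions(data)
  rows <- lapply(sessions, function(ses) {
    tab <- stay_table(ses)
    key <- paste0(substr(tab$transition, 1, 1),
                  ifelse(tab$reward == 1, "r", "u"))
    cells <- setNames(tab$p_stay, paste0("p_stay_", key))
    cnts <- setNames(tab$n_pairs, paste0("n_", key))
    data.frame(subject_id = ses$subject_id[1], timepoint = ses$timepoint[1],
               t(cells), t(cnts), mb1 = mb1_choice(ses), mb2 = mb2_rt(ses),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (hierarchical) {
    h <- hierarchical_scores(data)
    out <- merge(out, h, by = c("subject_id", "timepoint"), sort = FALSE)
  }
  out[order(out$subject_id, out$timepoint), , drop = FALSE]
}

#' Hierarchical (mixed-model) model-basedness scores
#'
#' @inheritParams twostep_scores
#' @param transition_coding value assigned to rare transitions in the RT
#'   model (common gets its negative). The default `+1` makes positive
#'   MB-II scores mean "slower after rare", i.e. more model-based, matching
#'   the sign of the individual score.
#' @return Data frame `subject_id`, `timepoint`, `mb1_h`, `mb2_h`.
#' @export
hierarchical_scores <- function(data, transition_coding = 1) {
  if (length(unique(data$subject_id)) < 2)
    stop("hierarchical scores need >= 2 subjects")
  out <- lapply(split(data, data$timepoint), function(tp) {
    mb1 <- tryCatch(h_mb1(tp), error = function(e) NULL)
    mb2 <- tryCatch(h_mb2(tp, transition_coding), error = function(e) NULL)
    ids <- unique(tp$subject_id)
    if (is.null(mb1)) {
      warning("mixed logistic did not converge; substituting individual MB-I")
      mb1 <- vapply(split(tp, tp$subject_id)[ids], mb1_choice, numeric(1))
    }
    if (is.null(mb2) && !all(is.na(tp$rt2_s))) {
      warning("mixed linear model failed; substituting individual MB-II")
      mb2 <- vapply(split(tp, tp$subject_id)[ids], mb2_rt, numeric(1))
    }
    if (is.null(mb2)) mb2 <- setNames(rep(NA_real_, length(ids)), ids)
    data.frame(subject_id = ids, timepoint = tp$timepoint[1],
               mb1_h = unname(mb1[ids]), mb2_h = unname(mb2[ids]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# mixed logistic: stay ~ prev transition * prev reward, -1/+1 coding
# (+1 = common, +1 = rewarded); subject-level interaction slope
h_mb1 <- function(tp) {
  pairs <- do.call(rbind, lapply(split_sessions(tp), function(ses) {
    pr <- stay_pairs(ses)
    if (nrow(pr)) pr$subject_id <- ses$subject_id[1]
    pr
  }))
  pairs$tr <- ifelse(pairs$transition == "common", 1, -1)
  pairs$rw <- ifelse(pairs$reward == 1, 1, -1)
  fit <- lme4::glmer(stay ~ tr * rw + (tr * rw | subject_id), data = pairs,
                     family = stats::binomial,
                     control = lme4::glmerControl(optimizer = "bobyqa",
                                                  calc.derivs = FALSE))
  cf <- stats::coef(fit)$subject_id
  setNames(cf[, "tr:rw"], rownames(cf))
}

# mixed linear: rt2 ~ transition (rare = +coding), subject-level slope
h_mb2 <- function(tp, coding = 1) {
  d <- tp[!is.na(tp$rt2_s), c("subject_id", "transition", "rt2_s")]
  if (!nrow(d)) stop("no RT data")
  d$tr <- ifelse(d$transition == "rare", coding, -coding)
  fit <- lme4::lmer(rt2_s ~ tr + (tr | subject_id), data = d,
                    control = lme4::lmerControl(optimizer = "bobyqa",
                                                calc.derivs = FALSE))
  cf <- stats::coef(fit)$subject_id
  setNames(cf[, "tr"], rownames(cf))
}

#' Effect size (eta squared) of the condition factor behind a score
#'
#' Classical (non-partial) eta squared from an ANOVA decomposition over
#' condition-cell means computed per subject and timepoint: for `"mb1"` the
#' transition x reward interaction on stay probability (cells from
#' [stay_table()]); for `"mb2"` the transition main effect on mean
#' second-stage RT.
#'
#' @param data multi-subject trial table.
#' @param score `"mb1"` or `"mb2"`.
#' @return Proportion of variance in \[0, 1\], or `NA` if degenerate.
#' @export
eta_squared <- function(data, score = c("mb1", "mb2")) {
  score <- match.arg(score)
  sessions <- split_sessions(data)
  if (score == "mb1") {
    cells <- do.call(rbind, lapply(sessions, function(ses) {
      tab <- stay_table(ses)
      tab$subject_id <- ses$subject_id[1]
      tab$timepoint <- ses$timepoint[1]
      tab
    }))
    cells <- cells[!is.na(cells$p_stay), ]
    if (stats::var(cells$p_stay) == 0) return(NA_real_)
    fit <- aov(p_stay ~ factor(transition) * factor(reward), data = cells)
    ss <- summary(fit)[[1]][["Sum Sq"]]
    term <- rownames(summary(fit)[[1]])
    eff <- ss[grepl(":", term)]
  } else {
    cells <- do.call(rbind, lapply(sessions, function(ses) {
      ag <- aggregate(rt2_s ~ transition, data = ses, FUN = mean)
      ag$subject_id <- ses$subject_id[1]
      ag$timepoint <- ses$timepoint[1]
      ag
    }))
    cells <- cells[!is.na(cells$rt2_s), ]
    if (nrow(cells) < 3 || stats::var(cells$rt2_s) == 0) return(NA_real_)
    fit <- aov(rt2_s ~ factor(transition), data = cells)
    ss <- summary(fit)[[1]][["Sum Sq"]]
    eff <- ss[1]
  }
  sum(eff) / sum(ss)
}
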