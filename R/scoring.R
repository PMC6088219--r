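#' Score the 12-item General Health Questionnaire (GHQ-12)
#'
#' Converts 12 item responses on the 4-point scale (0--3) into the
#' psychological-distress score. Under the default bimodal (GHQ) scoring,
#' responses 0/1 are recoded to 0 and responses 2/3 to 1, and the recoded
#' items are summed, so the total ranges from 0 to 12. Likert scoring
#' (plain sum of the 0--3 responses, range 0--36) is available via
#' `method = "likert"`.
#'
#' @param items Integer vector of length 12 with values in 0--3.
#' @param method `"bimodal"` (default) or `"likert"`.
#' @return Integer distress score: 0--12 (bimodal) or 0--36 (likert).
#' @examples
#' score_ghq12(rep(3L, 12))         # 12
#' score_ghq12(c(3,3,2,2,1,1,0,0,3,2,1,0))  # 6
#' @export
score_ghq12 <- function(items, method = c("bimodal", "likert")) {
  method <- match.arg(method)
  check_items(items, n = 12L, range = c(0L, 3L), instrument = "GHQ-12")
  if (method == "bimodal") sum(as.integer(items >= 2)) else sum(as.integer(items))
}

#' Score a HADS subscale
#'
#' Sums the 7 items (each 0--3) of a Hospital Anxiety and Depression Scale
#' subscale and flags probable disorder at the conventional cutoff of 8:
#' scores of 8 or more indicate disorder, 0--7 are normal. The maximum
#' subscale score is 21.
#'
#' @param items Integer vector of length 7 with values in 0--3.
#' @param cutoff Caseness cutoff; the flag is `score >= cutoff`. Default 8.
#' @return List with `score` (integer 0--21) and `disorder_flag` (logical).
#' @examples
#' score_hads(c(2, 2, 1, 1, 1, 1, 0))  # score 8, flagged
#' @export
score_hads <- function(items, cutoff = 8L) {
  check_items(items, n = 7L, range = c(0L, 3L), instrument = "HADS subscale")
  score <- sum(as.integer(items))
  list(score = score, disorder_flag = score >= cutoff)
}

#' Default codebook for the stressful life events questionnaire
#'
#' The 46 SLE items fall into 11 named domains; the item counts per domain
#' are (7, 5, 4, 5, 4, 4, 5, 4, 4, 2, 2) in the order below. Items are
#' referred to by index 1--46, assigned to domains consecutively.
#'
#' @return Named list mapping each domain to its item indices.
#' @export
sle_codebook <- function() {
  counts <- c(
    home_life = 7L, financial = 5L, social_relations = 4L,
    personal_conflict = 5L, job_conflicts = 4L, educational = 4L,
    job_security = 5L, loss_separation = 4L, sexual_life = 4L,
    daily_life = 2L, health_concerns = 2L
  )
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  stats::setNames(Map(seq.int, starts, ends), names(counts))
}

#' SLE domains belonging to each latent stressor factor
#'
#' The two-factor solution groups financial problems, social relations,
#' personal conflicts, job conflicts, educational concerns, job security
#' and daily life as socioeconomic stressors, and home life, loss and
#' separation, sexual life and health concerns as personal stressors.
#'
#' @return Named list with elements `socioeconomic` and `personal`.
#' @export
stressor_domains <- function() {
  list(
    socioeconomic = c("financial", "social_relations", "personal_conflict",
                      "job_conflicts", "educational", "job_security",
                      "daily_life"),
    personal = c("home_life", "loss_separation", "sexual_life",
                 "health_concerns")
  )
}

#' Score the stressful life events questionnaire into 11 domain scores
#'
#' Each of the 46 items is rated on a 6-point intensity scale
#' (0 never ... 5 very severe). A domain score is the mean of its items,
#' kept on the common 0--5 scale so domains with different item counts are
#' comparable; `aggregate = "sum"` returns raw item sums instead.
#'
#' @param items Integer vector of length 46 with values in 0--5.
#' @param codebook Named list mapping domains to item indices; must
#'   partition `1:46`. Default [sle_codebook()].
#' @param aggregate `"mean"` (default) or `"sum"`.
#' @return Named numeric vector of 11 domain scores.
#' @examples
#' x <- integer(46); x[sle_codebook()$home_life] <- c(3, 0, 0, 1, 2, 0, 1)
#' score_sle_domains(x)[["home_life"]]  # 1
#' @export
score_sle_domains <- function(items, codebook = sle_codebook(),
                              aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  check_items(items, n = 46L, range = c(0L, 5L), instrument = "SLE")
  idx <- unlist(codebook, use.names = FALSE)
  if (length(idx) != 46L || !setequal(idx, 1:46) || anyDuplicated(idx)) {
    stop("codebook must partition items 1..46 into domains", call. = FALSE)
  }
  fun <- if (aggregate == "mean") mean else sum
  vapply(codebook, function(ii) fun(items[ii]), numeric(1))
}

#' Effort-reward imbalance (ERI) ratio
#'
#' Computes the adjusted ratio of the effort sum to the reward sum,
#' `sum(effort) / (correction * sum(reward))`. The default correction of
#' 6/11 is the ratio of effort to reward item counts, so that identical
#' mean item responses on the two scales give a ratio of 1. Values above 1
#' indicate an effort-reward mismatch (job strain).
#'
#' @param effort Numeric vector of the 6 effort item scores.
#' @param reward Numeric vector of the 11 reward item scores.
#' @param correction Positive scale correction, default `6/11`.
#' @return Positive scalar ERI ratio.
#' @examples
#' score_eri(rep(2, 6), rep(2, 11))  # 1
#' @export
score_eri <- function(effort, reward, correction = 6 / 11) {
  if (!is.numeric(effort) || !is.numeric(reward)) {
    stop("effort and reward must be numeric", call. = FALSE)
  }
  if (!is.numeric(correction) || length(correction) != 1L || correction <= 0) {
    stop("correction must be a positive scalar", call. = FALSE)
  }
  se <- sum(effort); sr <- sum(reward)
  if (!isTRUE(sr > 0) || !isTRUE(se > 0)) {
    stop("effort and reward sums must be strictly positive", call. = FALSE)
  }
  se / (correction * sr)
}

#' Total physical activity from the IPAQ short form
#'
#' The total measure is the sum of the vigorous-activity, moderate-activity
#' and walking/sitting components, each already expressed in MET-hours per
#' week.
#'
#' @param vigorous_met,moderate_met,walk_sit_met Nonnegative components in
#'   MET-h/week.
#' @return Nonnegative total MET-h/week.
#' @export
score_ipaq <- function(vigorous_met, moderate_met, walk_sit_met) {
  comps <- c(vigorous_met, moderate_met, walk_sit_met)
  if (length(comps) != 3L || !is.numeric(comps) || anyNA(comps)) {
    stop("three numeric, non-missing components are required", call. = FALSE)
  }
  if (any(comps < 0)) stop("IPAQ components must be nonnegative", call. = FALSE)
  sum(comps)
}

# validate item vectors; names the first offending item
check_items <- function(items, n, range, instrument) {
  if (length(items) != n) {
    stop(sprintf("%s requires %d items, got %d", instrument, n, length(items)),
         call. = FALSE)
  }
  if (anyNA(items)) {
    stop(sprintf("%s item %d is missing", instrument, which(is.na(items))[1]),
         call. = FALSE)
  }
  bad <- which(items < range[1] | items > range[2] | items != round(items))
  if (length(bad)) {
    stop(sprintf("%s item %d response %s outside {%d..%d}", instrument,
                 bad[1], format(items[bad[1]]), range[1], range[2]),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a codebook mapping raw columns to instruments
#'
#' The codebook is a JSON object with entries `ghq12` (12 column names),
#' `hads_anxiety` and `hads_depression` (7 each), `sle` (46, in
#' [sle_codebook()] item order), `eri_effort` (6), `eri_reward` (11),
#' `ipaq` (3: vigorous, moderate, walk/sit) and `covariates` (named map of
#' covariate -> column).
#'
#' @param path Path to the JSON codebook.
#' @return Codebook list.
#' @export
read_codebook <- function(path) {
  cb <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("ghq12", "hads_anxiety", "hads_depression", "sle",
              "eri_effort", "eri_reward", "ipaq", "covariates")
  missing <- setdiff(needed, names(cb))
  if (length(missing)) {
    stop("codebook is missing entries: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cb
}

#' Score a raw participant table
#'
#' Applies all instrument scorers row by row. Item-level missingness below
#' the exclusion threshold is handled by prorated mean imputation within
#' instrument (the mean of the participant's answered items on that
#' instrument); participants missing more than `max_missing` of their
#' questionnaire items are flagged `excluded` and left unimputed.
#'
#' @param raw Data frame with one row per participant.
#' @param codebook Codebook list as returned by [read_codebook()].
#' @param max_missing Exclusion threshold on the fraction of missing
#'   questionnaire items, default 0.10.
#' @return Data frame with `ghq12_distress`, `hads_anxiety`,
#'   `hads_depression`, the 11 SLE domain scores, `eri_ratio`, `ipaq_met`,
#'   carried-through covariates, `missing_fraction` and `excluded`.
#' @export
score_participants <- function(raw, codebook, max_missing = 0.10) {
  stopifnot(is.data.frame(raw))
  item_cols <- c(codebook$ghq12, codebook$hads_anxiety,
                 codebook$hads_depression, codebook$sle,
                 codebook$eri_effort, codebook$eri_reward, codebook$ipaq)
  absent <- setdiff(item_cols, names(raw))
  if (length(absent)) {
    stop("raw table lacks columns named in codebook: ",
         paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  }

  impute <- function(x) {
    x <- as.numeric(x)
    if (anyNA(x)) x[is.na(x)] <- round(mean(x, na.rm = TRUE))
    x
  }

  n <- nrow(raw)
  miss_frac <- rowMeans(is.na(as.matrix(raw[item_cols])))
  excluded <- miss_frac > max_missing

  out <- data.frame(row.names = seq_len(n))
  dom_names <- names(sle_codebook())
  scores <- matrix(NA_real_, n, 5 + length(dom_names),
                   dimnames = list(NULL, c("ghq12_distress", "hads_anxiety",
                                           "hads_depression", dom_names,
                                           "eri_ratio", "ipaq_met")))
  for (i in seq_len(n)) {
    if (excluded[i]) next
    ghq <- impute(raw[i, codebook$ghq12])
    ha <- impute(raw[i, codebook$hads_anxiety])
    hd <- impute(raw[i, codebook$hads_depression])
    sle <- impute(raw[i, codebook$sle])
    eff <- impute(raw[i, codebook$eri_effort])
    rew <- impute(raw[i, codebook$eri_reward])
    ipaq <- impute(raw[i, codebook$ipaq])
    scores[i, "ghq12_distress"] <- score_ghq12(ghq)
    scores[i, "hads_anxiety"] <- score_hads(ha)$score
    scores[i, "hads_depression"] <- score_hads(hd)$score
    scores[i, dom_names] <- score_sle_domains(sle)
    scores[i, "eri_ratio"] <- score_eri(eff, rew)
    scores[i, "ipaq_met"] <- score_ipaq(ipaq[1], ipaq[2], ipaq[3])
  }
  out <- cbind(out, as.data.frame(scores))
  for (cv in names(codebook$covariates)) {
    out[[cv]] <- raw[[codebook$covariates[[cv]]]]
  }
  out$missing_fraction <- miss_frac
  out$excluded <- excluded
  out
}
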