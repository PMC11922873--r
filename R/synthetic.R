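# Synthetic FAERS-dialect data with known ground truth. Drugs are present
# independently per case; each reaction term is an independent Bernoulli
# draw whose probability is multiplied by a planted relative risk lambda
# when an associated drug is present (capped at 1). The recoverable
# reporting odds ratio approximates lambda only while background * lambda
# stays small (rare-event approximation); the generator warns beyond 0.1.

#' Default synthetic drug vocabulary
#'
#' Levodopa combination products (benserazide and carbidopa partners),
#' common concomitant anti-parkinsonian drugs, and non-PD background
#' medication. Columns: verbatim `drugname`, `prod_ai`, marginal presence
#' probability `p`, role distribution (`role_ps`, `role_ss`, `role_c`,
#' `role_i`), route distribution (`route_oral`, `route_nonoral`,
#' `route_unknown` with the non-oral raw string `nonoral_route`),
#' Parkinson's-indication probability `p_pd_ind` and the alternative
#' indication term `alt_indication`.
#'
#' @return tibble, one row per vocabulary drug
#' @export
default_drug_vocab <- function() {
  tibble::tribble(
    ~drugname, ~prod_ai, ~p, ~role_ps, ~role_ss, ~role_c, ~role_i,
    ~route_oral, ~route_nonoral, ~route_unknown, ~nonoral_route,
    ~p_pd_ind, ~alt_indication,
    "MADOPAR", "LEVODOPA\\BENSERAZIDE", 0.16, 0.70, 0.20, 0.10, 0.00,
    0.90, 0.04, 0.06, "INTRADUODENAL", 0.88, "Restless legs syndrome",
    "SINEMET", "LEVODOPA\\CARBIDOPA", 0.34, 0.70, 0.20, 0.10, 0.00,
    0.90, 0.04, 0.06, "INTESTINAL INFUSION", 0.88, "Restless legs syndrome",
    "STALEVO", "LEVODOPA\\CARBIDOPA\\ENTACAPONE", 0.05, 0.60, 0.25, 0.15,
    0.00, 0.92, 0.02, 0.06, "INTESTINAL INFUSION", 0.85,
    "Restless legs syndrome",
    "PRAMIPEXOLE", "PRAMIPEXOLE DIHYDROCHLORIDE", 0.10, 0.10, 0.15, 0.75,
    0.00, 0.90, 0.00, 0.10, "", 0.60, "Restless legs syndrome",
    "AMANTADINE", "AMANTADINE HYDROCHLORIDE", 0.05, 0.08, 0.12, 0.80, 0.00,
    0.90, 0.00, 0.10, "", 0.60, "Influenza",
    "RASAGILINE", "RASAGILINE MESYLATE", 0.05, 0.08, 0.12, 0.80, 0.00,
    0.90, 0.00, 0.10, "", 0.65, NA,
    "ROPINIROLE", "ROPINIROLE HYDROCHLORIDE", 0.04, 0.08, 0.12, 0.80, 0.00,
    0.90, 0.00, 0.10, "", 0.60, "Restless legs syndrome",
    "ROTIGOTINE", "ROTIGOTINE", 0.04, 0.08, 0.12, 0.80, 0.00,
    0.10, 0.85, 0.05, "TRANSDERMAL", 0.60, "Restless legs syndrome",
    "ENTACAPONE", "ENTACAPONE", 0.03, 0.05, 0.15, 0.80, 0.00,
    0.90, 0.00, 0.10, "", 0.70, NA,
    "ASPIRIN", "ASPIRIN", 0.20, 0.02, 0.03, 0.95, 0.00,
    0.85, 0.00, 0.15, "", 0.00, "Prophylaxis",
    "OMEPRAZOLE", "OMEPRAZOLE", 0.15, 0.02, 0.03, 0.95, 0.00,
    0.85, 0.00, 0.15, "", 0.00, "Gastrooesophageal reflux disease",
    "METFORMIN", "METFORMIN HYDROCHLORIDE", 0.10, 0.02, 0.03, 0.95, 0.00,
    0.85, 0.00, 0.15, "", 0.00, "Diabetes mellitus",
    "PARACETAMOL", "PARACETAMOL", 0.12, 0.02, 0.03, 0.95, 0.00,
    0.85, 0.00, 0.15, "", 0.00, "Pain"
  )
}

#' Default synthetic reaction-term vocabulary with background probabilities
#'
#' Includes the four motor-complication endpoint terms at low background
#' rates, terms exercising the screening exclusions (Parkinson's disease as
#' a reaction, dementia, psychotic disorder), and common background events
#' inside and outside the whitelisted system organ classes.
#'
#' @return tibble with columns `pt`, `p`
#' @export
default_pt_vocab <- function() {
  tibble::tribble(
    ~pt, ~p,
    "Dyskinesia", 0.010,
    "Dystonia", 0.004,
    "Tardive dyskinesia", 0.001,
    "On and off phenomenon", 0.004,
    "Freezing phenomenon", 0.004,
    "Therapeutic response shortened", 0.004,
    "Therapeutic response incomplete", 0.002,
    "Tremor", 0.050,
    "Somnolence", 0.040,
    "Dizziness", 0.070,
    "Headache", 0.060,
    "Gait disturbance", 0.030,
    "Fatigue", 0.080,
    "Asthenia", 0.040,
    "Drug ineffective", 0.090,
    "Condition aggravated", 0.030,
    "Parkinson's disease", 0.008,
    "Dementia", 0.006,
    "Psychotic disorder", 0.005,
    "Hallucination", 0.030,
    "Confusional state", 0.030,
    "Insomnia", 0.040,
    "Nausea", 0.110,
    "Vomiting", 0.060,
    "Constipation", 0.040,
    "Diarrhoea", 0.040,
    "Orthostatic hypotension", 0.020,
    "Fall", 0.070,
    "Hyperhidrosis", 0.015,
    "Weight decreased", 0.025,
    "Vision blurred", 0.015,
    "Dyspnoea", 0.030
  )
}

#' Default planted drug-event associations
#'
#' Relative risks on the endpoint terms mirroring the qualitative pattern
#' of interest: the benserazide partner loaded on dyskinesia and the on-off
#' phenomenon, the carbidopa partner on wearing-off, both elevated for
#' freezing.
#'
#' @return tibble with columns `drug_pattern`, `pt`, `lambda`
#' @export
default_associations <- function() {
  tibble::tribble(
    ~drug_pattern, ~pt, ~lambda,
    "benserazide", "Dyskinesia", 8,
    "benserazide", "On and off phenomenon", 22,
    "benserazide", "Freezing phenomenon", 15,
    "benserazide", "Therapeutic response shortened", 2.5,
    "carbidopa", "Dyskinesia", 6,
    "carbidopa", "On and off phenomenon", 10,
    "carbidopa", "Freezing phenomenon", 13,
    "carbidopa", "Therapeutic response shortened", 6
  )
}

#' Default synthetic demographics
#'
#' Weights over age bands, sexes, reporter occupation codes, reporter
#' country codes and serious-outcome codes, plus a log-normal body-weight
#' model (median ~70 kg) with missingness and a pound-denominated share.
#'
#' @return named list of weight vectors and scalar parameters
#' @export
default_demographics <- function() {
  list(
    age_band_w = c("<20" = 0.001, "20-50" = 0.02, "50-65" = 0.13,
                   ">=65" = 0.55, "unknown" = 0.299),
    sex_w = c(F = 0.45, M = 0.52, U = 0.03),
    reporter_w = c(MD = 0.18, CN = 0.55, OT = 0.10, PH = 0.09, LW = 0.002,
                   U = 0.078),
    country_w = c(US = 0.50, DE = 0.06, FR = 0.05, GB = 0.04, IT = 0.03,
                  ES = 0.02, JP = 0.05, BR = 0.012, AR = 0.005, CA = 0.05,
                  AU = 0.03, CN = 0.03, KR = 0.02, OTHER = 0.103),
    outcome_w = c(HO = 0.40, OT = 0.30, DE = 0.07, LT = 0.08, DS = 0.10,
                  CA = 0.005),
    outcome_k_w = c("0" = 0.15, "1" = 0.60, "2" = 0.25),
    wt_meanlog = log(70), wt_sdlog = 0.18,
    p_wt_missing = 0.30, p_wt_lbs = 0.20
  )
}

#' Configuration for the synthetic FAERS generator
#'
#' @param n_cases number of unique cases to generate
#' @param drug_vocab drug vocabulary, see [default_drug_vocab()]
#' @param pt_vocab reaction-term vocabulary, see [default_pt_vocab()]
#' @param associations planted drug-event relative risks, see
#'   [default_associations()]; set to a zero-row tibble for full
#'   independence
#' @param demographics demographic weights, see [default_demographics()]
#' @param duplicate_fraction fraction of cases re-emitted as a second case
#'   version (FAERS multi-quarter duplication), in `[0, 1)`
#' @param planted_stages optional screening-stage targets set via
#'   [plant_flowchart()]
#' @return a `synthetic_config` object
#' @export
synthetic_config <- function(n_cases = 5000,
                             drug_vocab = default_drug_vocab(),
                             pt_vocab = default_pt_vocab(),
                             associations = default_associations(),
                             demographics = default_demographics(),
                             duplicate_fraction = 0.05,
                             planted_stages = NULL) {
  stopifnot(n_cases >= 1, nrow(drug_vocab) >= 1, nrow(pt_vocab) >= 1,
            duplicate_fraction >= 0, duplicate_fraction < 1,
            all(pt_vocab$p >= 0 & pt_vocab$p <= 1),
            all(drug_vocab$p >= 0 & drug_vocab$p <= 1))
  if (nrow(associations) > 0) {
    stopifnot(all(associations$lambda > 0),
              all(associations$pt %in% pt_vocab$pt))
    risky <- associations$lambda *
      pt_vocab$p[match(associations$pt, pt_vocab$pt)] > 0.1
    if (any(risky)) {
      warning("synthetic_config: background * lambda exceeds 0.1 for ",
              sum(risky), " association(s); the rare-event approximation ",
              "ROR ~ lambda degrades", call. = FALSE)
    }
  }
  structure(list(n_cases = as.integer(n_cases), drug_vocab = drug_vocab,
                 pt_vocab = pt_vocab, associations = associations,
                 demographics = demographics,
                 duplicate_fraction = duplicate_fraction,
                 planted_stages = planted_stages),
            class = "synthetic_config")
}

#' Plant exact screening-stage counts into a configuration
#'
#' Adjusts drug, route, indication and reaction assignment of the first
#' target drug (the benserazide partner by default) so that the screening
#' cascade's trace for that drug equals `stage_targets` exactly:
#' `c(drug_match, oral_route, pd_indication, soc)`.
#'
#' @param config a [synthetic_config()]
#' @param stage_targets non-increasing integer vector of length 4, all at
#'   most `n_cases`
#' @return the modified `synthetic_config`
#' @export
plant_flowchart <- function(config, stage_targets) {
  stopifnot(inherits(config, "synthetic_config"))
  t <- as.integer(stage_targets)
  if (length(t) != 4L || any(is.na(t)) || any(t < 0)) {
    stop("plant_flowchart: stage_targets must be 4 nonnegative integers",
         call. = FALSE)
  }
  if (any(diff(t) > 0)) {
    stop("plant_flowchart: stage_targets must be non-increasing",
         call. = FALSE)
  }
  if (t[1] > config$n_cases) {
    stop("plant_flowchart: first stage target exceeds n_cases",
         call. = FALSE)
  }
  config$planted_stages <- t
  config
}

sample_w <- function(n, w) sample(names(w), n, replace = TRUE,
                                  prob = unname(w))

#' Generate a synthetic FAERS-dialect dataset with ground truth
#'
#' Draws drugs, reactions, indications, demographics and outcomes for
#' `n_cases` unique cases, re-emits `duplicate_fraction` of them as a
#' second case version, and (optionally) writes the six FAERS-dialect
#' files. All randomness derives from `seed`; the same configuration and
#' seed reproduce the output exactly.
#'
#' @param config a [synthetic_config()]
#' @param seed integer seed
#' @param dir optional directory; when given, the quarter files are written
#'   there via [write_quarter()]
#' @param quarter quarter label for the file stems
#' @return list with `raw` (a `faers_raw` of the emitted string tables,
#'   duplicates included), `truth` (ground truth: `n_unique`,
#'   `eligibility` flags per case and query, `pair_counts` for the planted
#'   associations, `stage_counts`), and `paths` (written files or `NULL`)
#' @export
generate_synthetic_faers <- function(config, seed, dir = NULL,
                                     quarter = "24Q1") {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n <- config$n_cases
  dv <- config$drug_vocab
  pv <- config$pt_vocab
  K <- nrow(dv); M <- nrow(pv)
  demo_w <- config$demographics

  caseid <- as.character(90000000 + seq_len(n))

  ## drug presence, roles, routes -------------------------------------
  pres <- matrix(runif(n * K), n, K) < rep(dv$p, each = n)
  role_m <- matrix(NA_character_, n, K)
  route_m <- matrix(NA_character_, n, K)
  planted <- config$planted_stages
  plant_idx <- NULL
  if (!is.null(planted)) {
    plant_idx <- which(match_any_pattern(
      default_drug_queries()[[1]]$name_patterns, dv$drugname, dv$prod_ai))[1]
    if (is.na(plant_idx)) {
      stop("plant_flowchart: no vocabulary drug matches the first query",
           call. = FALSE)
    }
    pres[, plant_idx] <- seq_len(n) <= planted[1]
  }
  # a report lists at least one drug
  none <- rowSums(pres) == 0L
  if (any(none)) {
    filler_drug <- which(dv$p_pd_ind == 0)[1]
    if (is.na(filler_drug)) filler_drug <- K
    pres[none, filler_drug] <- TRUE
  }
  for (k in seq_len(K)) {
    idx <- which(pres[, k])
    if (length(idx) == 0L) next
    role_m[idx, k] <- sample_w(length(idx),
                               c(PS = dv$role_ps[k], SS = dv$role_ss[k],
                                 C = dv$role_c[k], I = dv$role_i[k]))
    route_m[idx, k] <- sample_w(length(idx), stats::setNames(
      c(dv$route_oral[k], dv$route_nonoral[k], dv$route_unknown[k]),
      c("ORAL", if (nzchar(dv$nonoral_route[k])) dv$nonoral_route[k]
        else "OTHER_NONORAL", "UNKNOWN")))
    route_m[idx, k][route_m[idx, k] == "UNKNOWN"] <- ""
  }
  if (!is.null(planted)) {
    sel <- seq_len(n) <= planted[1]
    role_m[sel, plant_idx] <- "PS"
    route_m[sel, plant_idx] <-
      ifelse(seq_len(n)[sel] <= planted[2], "ORAL", dv$nonoral_route[plant_idx])
  }

  ## indications per present drug row ---------------------------------
  ind_m <- matrix(NA_character_, n, K)
  for (k in seq_len(K)) {
    idx <- which(pres[, k])
    if (length(idx) == 0L) next
    u <- runif(length(idx))
    pd <- u < dv$p_pd_ind[k]
    ind <- rep(NA_character_, length(idx))
    ind[pd] <- ifelse(runif(sum(pd)) < 0.1, "Idiopathic Parkinson's disease",
                      "Parkinson's disease")
    alt <- !pd & u < dv$p_pd_ind[k] + 0.25 & !is.na(dv$alt_indication[k])
    ind[alt] <- dv$alt_indication[k]
    ind_m[idx, k] <- ind
  }

  ## reaction draws ----------------------------------------------------
  prob <- matrix(rep(pv$p, each = n), n, M)
  if (nrow(config$associations) > 0) {
    # lambda is the relative risk given that an associated drug is present;
    # when several associated drugs co-occur the strongest applies (they do
    # not compound)
    mult <- matrix(1, n, M)
    for (i in seq_len(nrow(config$associations))) {
      as_row <- config$associations[i, ]
      didx <- which(match_any_pattern(as_row$drug_pattern, dv$drugname,
                                      dv$prod_ai))
      if (length(didx) == 0L) next
      affected <- rowSums(pres[, didx, drop = FALSE]) > 0L
      pidx <- match(as_row$pt, pv$pt)
      mult[affected, pidx] <- pmax(mult[affected, pidx], as_row$lambda)
    }
    prob <- prob * mult
  }
  capped <- prob > 1
  if (any(capped)) {
    message("generate_synthetic_faers: capped ", sum(capped),
            " reaction probability value(s) at 1")
    prob[capped] <- 1
  }
  reac_draw <- matrix(runif(n * M), n, M) < prob

  pd_react_terms <- canonical_pt(load_pd_indications())
  excl_patterns <- load_exclusion_patterns()
  pt_soc <- load_pt_soc()
  soc_white <- default_soc_whitelist()
  pt_canon <- canonical_pt(pv$pt)
  pt_white <- pt_soc$soc[match(pt_canon, pt_soc$pt)] %in% soc_white
  pt_excl <- match_any_pattern(excl_patterns, pt_canon) |
    pt_canon %in% pd_react_terms

  if (!is.null(planted)) {
    s1 <- planted[1]; s2 <- planted[2]; s3 <- planted[3]; s4 <- planted[4]
    # indication stage: first s3 get a clean PD indication on the planted
    # drug and no excluding reactions; s3+1..s2 lose it
    ind_m[seq_len(min(s3, n)), plant_idx] <- "Parkinson's disease"
    if (s3 < s2) {
      # strip PD indications from every drug of the cases meant to fail the
      # indication stage (a PD term on any matched partner row would pass)
      blk <- ind_m[(s3 + 1):s2, , drop = FALSE]
      blk[canonical_pt(blk) %in% pd_react_terms] <- NA_character_
      ind_m[(s3 + 1):s2, ] <- blk
    }
    if (s3 >= 1) reac_draw[seq_len(s3), pt_excl] <- FALSE
    # SOC stage: first s4 get a whitelisted-SOC reaction; s4+1..s3 lose all
    dysk <- match(canonical_pt("Dyskinesia"), pt_canon)
    nau <- match(canonical_pt("Nausea"), pt_canon)
    if (s4 >= 1) {
      need <- seq_len(s4)[rowSums(reac_draw[seq_len(s4), pt_white,
                                            drop = FALSE]) == 0L]
      reac_draw[need, dysk] <- TRUE
    }
    if (s4 < s3) {
      reac_draw[(s4 + 1):s3, pt_white] <- FALSE
      reac_draw[(s4 + 1):s3, nau] <- TRUE
    }
  }

  # a report carries at least one reaction; the filler is a non-whitelisted,
  # non-excluding term so screening semantics are unchanged
  no_reac <- rowSums(reac_draw) == 0L
  if (any(no_reac)) {
    filler_pt <- which(!pt_white & !pt_excl)[1]
    reac_draw[no_reac, filler_pt] <- TRUE
  }

  ## demographics -------------------------------------------------------
  band <- sample_w(n, demo_w$age_band_w)
  age_years <- rep(NA_real_, n)
  rng <- list("<20" = c(5, 19), "20-50" = c(20, 49), "50-65" = c(50, 64),
              ">=65" = c(65, 90))
  for (b in names(rng)) {
    idx <- which(band == b)
    if (length(idx)) {
      age_years[idx] <- floor(runif(length(idx), rng[[b]][1],
                                    rng[[b]][2] + 1))
    }
  }
  age_str <- ifelse(is.na(age_years), "", as.character(age_years))
  age_cod <- ifelse(is.na(age_years), "", "YR")
  # a few ages in months / decades exercise unit harmonization
  u_unit <- runif(n)
  mon <- !is.na(age_years) & u_unit < 0.05
  age_str[mon] <- as.character(age_years[mon] * 12)
  age_cod[mon] <- "MON"
  dec <- !is.na(age_years) & u_unit >= 0.05 & u_unit < 0.07
  age_str[dec] <- as.character(age_years[dec] / 10)
  age_cod[dec] <- "DEC"

  sex <- sample_w(n, demo_w$sex_w)
  sex[sex == "U"] <- ""
  occp <- sample_w(n, demo_w$reporter_w)
  occp[occp == "U"] <- ""
  country <- sample_w(n, demo_w$country_w)
  country[country == "OTHER"] <- "XX"

  wt_kg <- rlnorm(n, demo_w$wt_meanlog, demo_w$wt_sdlog)
  wt_missing <- runif(n) < demo_w$p_wt_missing
  wt_lbs <- !wt_missing & runif(n) < demo_w$p_wt_lbs
  wt_str <- ifelse(wt_missing, "",
                   ifelse(wt_lbs, sprintf("%.1f", wt_kg / 0.453592),
                          sprintf("%.1f", wt_kg)))
  wt_cod <- ifelse(wt_missing, "", ifelse(wt_lbs, "LBS", "KG"))

  yearq <- sample(0:81, n, replace = TRUE)  # 2004Q1 .. 2024Q2 span
  yr <- 2004 + yearq %/% 4
  qt <- yearq %% 4
  keep_span <- yr < 2024 | qt < 2
  yearq[!keep_span] <- yearq[!keep_span] - 2
  yr <- 2004 + yearq %/% 4; qt <- yearq %% 4
  event_dt <- sprintf("%04d%02d%02d", yr, qt * 3 + 1,
                      sample(1:28, n, replace = TRUE))

  ## assemble FAERS-dialect string tables -------------------------------
  primaryid <- paste0(caseid, "1")
  demo_tbl <- tibble::tibble(
    primaryid = primaryid, caseid = caseid, caseversion = "1",
    event_dt = event_dt, age = age_str, age_cod = age_cod, sex = sex,
    wt = wt_str, wt_cod = wt_cod, reporter_country = country,
    occp_cod = occp)

  pres_idx <- which(pres, arr.ind = TRUE)
  pres_idx <- pres_idx[order(pres_idx[, 1], pres_idx[, 2]), , drop = FALSE]
  ci <- pres_idx[, 1]; ki <- pres_idx[, 2]
  drug_seq <- stats::ave(ci, ci, FUN = seq_along)
  drug_tbl <- tibble::tibble(
    primaryid = primaryid[ci], caseid = caseid[ci],
    drug_seq = as.character(drug_seq),
    role_cod = role_m[cbind(ci, ki)],
    drugname = dv$drugname[ki], prod_ai = dv$prod_ai[ki],
    route = route_m[cbind(ci, ki)])

  reac_idx <- which(reac_draw, arr.ind = TRUE)
  reac_idx <- reac_idx[order(reac_idx[, 1], reac_idx[, 2]), , drop = FALSE]
  reac_tbl <- tibble::tibble(
    primaryid = primaryid[reac_idx[, 1]], caseid = caseid[reac_idx[, 1]],
    pt = pv$pt[reac_idx[, 2]])

  has_ind <- !is.na(ind_m[cbind(ci, ki)])
  indi_tbl <- tibble::tibble(
    primaryid = primaryid[ci][has_ind], caseid = caseid[ci][has_ind],
    indi_drug_seq = as.character(drug_seq[has_ind]),
    indi_pt = ind_m[cbind(ci, ki)][has_ind])

  k_out <- as.integer(sample_w(n, demo_w$outcome_k_w))
  oc1 <- sample_w(n, demo_w$outcome_w)
  oc2 <- sample_w(n, demo_w$outcome_w)
  out_rows <- list(
    tibble::tibble(primaryid = primaryid[k_out >= 1],
                   caseid = caseid[k_out >= 1], outc_cod = oc1[k_out >= 1]),
    tibble::tibble(primaryid = primaryid[k_out >= 2 & oc2 != oc1],
                   caseid = caseid[k_out >= 2 & oc2 != oc1],
                   outc_cod = oc2[k_out >= 2 & oc2 != oc1]))
  outc_tbl <- dplyr::bind_rows(out_rows)
  outc_tbl <- outc_tbl[order(outc_tbl$caseid), , drop = FALSE]

  rpsr_tbl <- tibble::tibble(primaryid = primaryid, caseid = caseid,
                             rpsr_cod = sample_w(n, c(FGN = 0.3, MFR = 0.5,
                                                      DIR = 0.2)))

  ## duplicates: re-emit a fraction as case version 2 --------------------
  n_dup <- floor(config$duplicate_fraction * n)
  if (n_dup > 0) {
    dup_rows <- sort(sample(n, n_dup))
    dup_case <- caseid[dup_rows]
    bump <- function(tb) {
      d <- tb[tb$caseid %in% dup_case, , drop = FALSE]
      d$primaryid <- paste0(d$caseid, "2")
      if ("caseversion" %in% names(d)) d$caseversion <- "2"
      d
    }
    demo_tbl <- dplyr::bind_rows(demo_tbl, bump(demo_tbl))
    drug_tbl <- dplyr::bind_rows(drug_tbl, bump(drug_tbl))
    reac_tbl <- dplyr::bind_rows(reac_tbl, bump(reac_tbl))
    indi_tbl <- dplyr::bind_rows(indi_tbl, bump(indi_tbl))
    outc_tbl <- dplyr::bind_rows(outc_tbl, bump(outc_tbl))
    rpsr_tbl <- dplyr::bind_rows(rpsr_tbl, bump(rpsr_tbl))
  }

  raw <- structure(list(demo = demo_tbl, drug = drug_tbl, reac = reac_tbl,
                        indi = indi_tbl, outc = outc_tbl, rpsr = rpsr_tbl),
                   class = "faers_raw", rejects = list())

  truth <- synthetic_truth(config, caseid, pres, role_m, route_m, ind_m,
                           reac_draw, pt_canon, pt_white, pt_excl,
                           pd_react_terms, excl_patterns)

  paths <- NULL
  if (!is.null(dir)) paths <- write_quarter(raw, dir, quarter)
  list(raw = raw, truth = truth, paths = paths)
}

# ground-truth eligibility flags and drug-event pair counts, computed from
# the realized draw matrices with the same semantics as the screening
# cascade
synthetic_truth <- function(config, caseid, pres, role_m, route_m, ind_m,
                            reac_draw, pt_canon, pt_white, pt_excl,
                            pd_react_terms, excl_patterns) {
  dv <- config$drug_vocab
  n <- length(caseid)
  queries <- default_drug_queries()
  suspect <- !is.na(role_m) & role_m %in% c("PS", "SS")
  oral <- !is.na(route_m) & route_m == "ORAL"
  pd_ind <- !is.na(ind_m) & canonical_pt(ind_m) %in% pd_react_terms
  excl_ind <- !is.na(ind_m) & match_any_pattern(excl_patterns,
                                                as.vector(ind_m))
  dim(excl_ind) <- dim(ind_m)

  any_pd_reaction <- rowSums(reac_draw[, pt_canon %in% pd_react_terms,
                                       drop = FALSE]) > 0L
  any_excl_reaction <- rowSums(reac_draw[, pt_excl & !(pt_canon %in%
                                                         pd_react_terms),
                                         drop = FALSE]) > 0L
  soc_ok <- rowSums(reac_draw[, pt_white, drop = FALSE]) > 0L

  elig <- tibble::tibble(caseid = caseid)
  for (lab in names(queries)) {
    q <- queries[[lab]]
    tgt_idx <- which(match_any_pattern(q$name_patterns, dv$drugname,
                                       dv$prod_ai))
    par_idx <- which(match_any_pattern(q$required_partner_patterns,
                                       dv$drugname, dv$prod_ai))
    tgt_sus <- suspect[, tgt_idx, drop = FALSE]
    par_sus <- suspect[, par_idx, drop = FALSE]
    match_q <- rowSums(tgt_sus) > 0L & rowSums(par_sus) > 0L
    oral_q <- rowSums(tgt_sus & oral[, tgt_idx, drop = FALSE]) > 0L &
      rowSums(par_sus & oral[, par_idx, drop = FALSE]) > 0L
    both_idx <- union(tgt_idx, par_idx)
    matched_sus <- suspect[, both_idx, drop = FALSE]
    pd_q <- rowSums(matched_sus & pd_ind[, both_idx, drop = FALSE]) > 0L &
      !any_pd_reaction & !any_excl_reaction &
      rowSums(excl_ind) == 0L
    elig[[paste0(lab, "_match")]] <- match_q
    elig[[paste0(lab, "_oral")]] <- match_q & oral_q
    elig[[paste0(lab, "_pd")]] <- match_q & oral_q & pd_q
    elig[[paste0(lab, "_eligible")]] <- match_q & oral_q & pd_q & soc_ok
  }
  elig$soc_ok <- soc_ok

  pair_counts <- NULL
  if (nrow(config$associations) > 0) {
    rows <- lapply(seq_len(nrow(config$associations)), function(i) {
      as_row <- config$associations[i, ]
      didx <- which(match_any_pattern(as_row$drug_pattern, dv$drugname,
                                      dv$prod_ai))
      with_drug <- rowSums(pres[, didx, drop = FALSE]) > 0L
      with_pt <- reac_draw[, match(as_row$pt, config$pt_vocab$pt)]
      tibble::tibble(drug_pattern = as_row$drug_pattern, pt = as_row$pt,
                     lambda = as_row$lambda,
                     a = sum(with_drug & with_pt),
                     b = sum(with_drug & !with_pt),
                     c = sum(!with_drug & with_pt),
                     d = sum(!with_drug & !with_pt))
    })
    pair_counts <- dplyr::bind_rows(rows)
  }

  first_lab <- names(queries)[1]
  stage_counts <- c(
    input = n,
    drug_match = sum(elig[[paste0(first_lab, "_match")]]),
    oral_route = sum(elig[[paste0(first_lab, "_oral")]]),
    pd_indication = sum(elig[[paste0(first_lab, "_pd")]]),
    soc = sum(elig[[paste0(first_lab, "_eligible")]]))

  list(n_unique = n, eligibility = elig, pair_counts = pair_counts,
       stage_counts = stage_counts)
}

#' Configuration for estimator-recovery studies
#'
#' A reduced design for measuring how well the pipeline recovers a planted
#' relative risk: one association (the benserazide partner on the on-off
#' phenomenon term) at relative risk `lambda`, with the exposed drug
#' always a suspect, always oral and always carrying the Parkinson's
#' indication, no excluding background terms, and a high-probability
#' whitelisted background term so the SOC stage retains essentially every
#' report. This keeps the screening cascade from conditioning the exposed
#' cohort on the outcome: with lossy screening the retained exposed set is
#' enriched for whitelisted events by construction and the odds ratio no
#' longer estimates `lambda`. The endpoint background probability is
#' `0.03 / lambda`, so the endpoint rate among exposed reports is 3% for
#' every `lambda` (rare-event regime, expected exposed count ~60 at the
#' default size).
#'
#' The default size grows with `lambda` so that the expected endpoint count
#' is at least ~30 in the comparator arm as well as the exposed arm; below
#' that the odds-ratio estimator's small-sample skew (driven by the
#' reciprocal of the comparator count) biases its mean upward.
#'
#' @param lambda planted relative risk (`1` gives the null design)
#' @param n_cases number of unique cases; default `max(6000, 1600 * lambda)`
#' @return a `synthetic_config`
#' @export
estimator_recovery_config <- function(lambda,
                                      n_cases = max(6000, 1600 * lambda)) {
  stopifnot(lambda > 0)
  dv <- tibble::tribble(
    ~drugname, ~prod_ai, ~p, ~role_ps, ~role_ss, ~role_c, ~role_i,
    ~route_oral, ~route_nonoral, ~route_unknown, ~nonoral_route,
    ~p_pd_ind, ~alt_indication,
    "MADOPAR", "LEVODOPA\\BENSERAZIDE", 0.35, 1.0, 0.0, 0.0, 0.0,
    1.0, 0.0, 0.0, "", 1.0, NA,
    "SINEMET", "LEVODOPA\\CARBIDOPA", 0.25, 0.9, 0.1, 0.0, 0.0,
    0.95, 0.02, 0.03, "INTESTINAL INFUSION", 0.95, NA,
    "OMEPRAZOLE", "OMEPRAZOLE", 0.30, 0.02, 0.03, 0.95, 0.00,
    0.85, 0.00, 0.15, "", 0.00, "Gastrooesophageal reflux disease"
  )
  pv <- tibble::tribble(
    ~pt, ~p,
    "On and off phenomenon", 0.03 / lambda,
    "Fatigue", 0.97,
    "Dizziness", 0.50,
    "Nausea", 0.20,
    "Fall", 0.10
  )
  assoc <- tibble::tibble(drug_pattern = "benserazide",
                          pt = "On and off phenomenon", lambda = lambda)
  if (lambda == 1) assoc <- assoc[0, ]
  synthetic_config(n_cases = n_cases, drug_vocab = dv, pt_vocab = pv,
                   associations = assoc, duplicate_fraction = 0.02)
}
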