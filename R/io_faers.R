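# FAERS quarterly ASCII dialect: one header line, $-delimited, no quoting.
# Post-2012 column layout only.

faers_mandatory_columns <- list(
  demo = c("primaryid", "caseid", "caseversion", "event_dt", "age", "age_cod",
           "sex", "wt", "wt_cod", "reporter_country", "occp_cod"),
  drug = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname",
           "prod_ai", "route"),
  reac = c("primaryid", "caseid", "pt"),
  indi = c("primaryid", "caseid", "indi_drug_seq", "indi_pt"),
  outc = c("primaryid", "caseid", "outc_cod"),
  rpsr = c("primaryid", "caseid", "rpsr_cod")
)

#' Locate the six FAERS-dialect files of one quarter
#'
#' Files follow the FAERS stems `DEMOyyQq.txt`, `DRUGyyQq.txt`, ... Matching
#' is case-insensitive on the stem.
#'
#' @param dir directory holding the quarter's files
#' @param quarter optional quarter label such as `"24Q1"`; when `NULL`, any
#'   single file per stem is accepted
#' @return named character vector of paths (names `demo`, `drug`, `reac`,
#'   `indi`, `outc`, `rpsr`)
#' @export
faers_quarter_paths <- function(dir, quarter = NULL) {
  stems <- c(demo = "DEMO", drug = "DRUG", reac = "REAC",
             indi = "INDI", outc = "OUTC", rpsr = "RPSR")
  out <- vapply(stems, function(s) {
    pat <- if (is.null(quarter)) paste0("^", s, ".*\\.(txt|TXT)$")
           else paste0("^", s, quarter, "\\.(txt|TXT)$")
    hits <- list.files(dir, pattern = pat, ignore.case = TRUE,
                       full.names = TRUE)
    if (length(hits) == 0L) NA_character_ else hits[[1L]]
  }, character(1))
  out
}

read_faers_file <- function(path, table) {
  lines <- readLines(path, warn = FALSE)
  bad <- !validUTF8(lines)
  if (any(bad)) lines[bad] <- iconv(lines[bad], "latin1", "UTF-8")
  d <- utils::read.delim(text = paste(lines, collapse = "\n"), sep = "$",
                         quote = "", colClasses = "character",
                         check.names = FALSE, stringsAsFactors = FALSE)
  names(d) <- tolower(trimws(names(d)))
  need <- faers_mandatory_columns[[table]]
  missing <- setdiff(need, names(d))
  if (length(missing) > 0L) {
    stop(sprintf("FAERS %s file %s is missing mandatory column(s): %s",
                 toupper(table), basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(d) != length(lines) - 1L) {
    stop(sprintf("FAERS %s file %s: parsed %d rows from %d data lines",
                 toupper(table), basename(path), nrow(d),
                 length(lines) - 1L), call. = FALSE)
  }
  tibble::as_tibble(d)
}

#' Read one FAERS-dialect quarter into raw linked tables
#'
#' Parses the six dollar-delimited ASCII tables (DEMO, DRUG, REAC, INDI,
#' OUTC, RPSR) of one quarter. Empty fields are kept as empty strings
#' ("unknown") at this stage; normalization happens in [deduplicate()].
#' Child rows whose `primaryid` does not appear in DEMO are moved to a
#' rejects report (attribute `rejects`) rather than failing the read.
#'
#' @param paths named character vector of file paths as returned by
#'   [faers_quarter_paths()]; `indi`, `outc`, `rpsr` may be `NA` (treated
#'   as empty tables)
#' @return a `faers_raw` object: list of tibbles `demo`, `drug`, `reac`,
#'   `indi`, `outc`, `rpsr`, with attribute `rejects` (orphan child rows)
#' @export
read_quarter <- function(paths) {
  need <- c("demo", "drug", "reac")
  if (!all(need %in% names(paths)) || any(is.na(paths[need]))) {
    stop("read_quarter: paths must name existing demo, drug and reac files",
         call. = FALSE)
  }
  tabs <- list()
  for (tb in names(faers_mandatory_columns)) {
    p <- paths[[tb]] %||% NA_character_
    if (is.na(p)) {
      cols <- faers_mandatory_columns[[tb]]
      tabs[[tb]] <- tibble::as_tibble(stats::setNames(
        as.data.frame(matrix(character(0), 0, length(cols))), cols))
    } else {
      if (!file.exists(p)) stop("read_quarter: file not found: ", p,
                                call. = FALSE)
      tabs[[tb]] <- read_faers_file(p, tb)
    }
  }
  known <- unique(tabs$demo$primaryid)
  rejects <- list()
  for (tb in c("drug", "reac", "indi", "outc", "rpsr")) {
    orphan <- !(tabs[[tb]]$primaryid %in% known)
    if (any(orphan)) {
      rejects[[tb]] <- tabs[[tb]][orphan, , drop = FALSE]
      tabs[[tb]] <- tabs[[tb]][!orphan, , drop = FALSE]
    }
  }
  if (length(rejects) > 0L) {
    message("read_quarter: ", sum(vapply(rejects, nrow, integer(1))),
            " orphan child row(s) moved to the rejects report")
  }
  structure(tabs, class = "faers_raw", rejects = rejects)
}

#' @export
print.faers_raw <- function(x, ...) {
  cat("<faers_raw>\n")
  for (tb in names(faers_mandatory_columns)) {
    cat(sprintf("  %s: %d rows\n", toupper(tb), nrow(x[[tb]])))
  }
  rej <- attr(x, "rejects")
  if (length(rej) > 0L) {
    cat("  rejects:", sum(vapply(rej, nrow, integer(1))), "orphan rows\n")
  }
  invisible(x)
}

#' Combine the raw tables of several quarters
#'
#' @param ... `faers_raw` objects
#' @return one `faers_raw` with rows stacked
#' @export
bind_quarters <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1), "faers_raw")))
  out <- lapply(stats::setNames(nm = names(faers_mandatory_columns)),
                function(tb) dplyr::bind_rows(lapply(parts, `[[`, tb)))
  structure(out, class = "faers_raw", rejects = list())
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

harmonize_age_years <- function(age, age_cod) {
  v <- num_or_na(age)
  cod <- toupper(trimws(age_cod))
  mult <- rep(NA_real_, length(v))
  mult[cod %in% c("YR", "YEAR", "YRS")] <- 1
  mult[cod == "DEC"] <- 10
  mult[cod %in% c("MON", "MONTH")] <- 1 / 12
  mult[cod %in% c("WK", "WEEK")] <- 7 / 365.25
  mult[cod %in% c("DY", "DAY")] <- 1 / 365.25
  mult[cod == "HR"] <- 1 / (24 * 365.25)
  # missing unit with a plausible-year value: treat as years
  mult[(is.na(mult) | cod == "") & !is.na(v) & v > 0 & v <= 120] <- 1
  yrs <- v * mult
  yrs[!is.na(yrs) & (yrs < 0 | yrs > 120)] <- NA_real_
  yrs
}

#' Assign the study's age bands
#'
#' Bands: `<20`, `20-50` (20 <= age < 50), `50-65` (50 <= age < 65), `>=65`,
#' `unknown` for missing age.
#'
#' @param age_years numeric vector of ages in years (NA = unknown)
#' @return character vector of band labels
#' @export
age_band <- function(age_years) {
  out <- rep("unknown", length(age_years))
  ok <- !is.na(age_years)
  out[ok & age_years < 20] <- "<20"
  out[ok & age_years >= 20 & age_years < 50] <- "20-50"
  out[ok & age_years >= 50 & age_years < 65] <- "50-65"
  out[ok & age_years >= 65] <- ">=65"
  out
}

harmonize_weight_kg <- function(wt, wt_cod) {
  v <- num_or_na(wt)
  cod <- toupper(trimws(wt_cod))
  v[cod %in% c("LBS", "LB")] <- v[cod %in% c("LBS", "LB")] * 0.453592
  v[cod == "GMS"] <- v[cod == "GMS"] / 1000
  # FAERS entry noise: implausible body weights treated as unknown
  v[!is.na(v) & (v <= 20 | v >= 300)] <- NA_real_
  v
}

role_map <- c(PS = "suspect_primary", SS = "suspect_secondary",
              C = "concomitant", I = "interacting")

outcome_map <- c(HO = "hospitalization", LT = "life_threatening",
                 DE = "death", DS = "disability", CA = "congenital_anomaly",
                 OT = "other_serious", RI = "other_serious")

parse_event_date <- function(x) {
  x <- trimws(x)
  full <- grepl("^[0-9]{8}$", x)
  out <- rep(as.Date(NA), length(x))
  out[full] <- as.Date(x[full], format = "%Y%m%d")
  out
}

#' Deduplicate FAERS case versions and build harmonized case records
#'
#' FAERS re-publishes a case across quarters as new versions. Per FDA
#' guidance, one record per `caseid` is retained: the highest
#' `caseversion`, ties broken by the highest `primaryid`. The retained
#' version's child rows (drugs, reactions, indications, outcomes) are
#' carried; other versions are dropped entirely. Fields are harmonized on
#' the way out: ages to years, weights to kg, routes/roles/reporter
#' occupations/countries to closed vocabularies, preferred terms to
#' canonical case.
#'
#' Applying `deduplicate()` to an already-deduplicated case set is the
#' identity.
#'
#' @param x a `faers_raw` (from [read_quarter()]) or `faers_cases` object
#' @param ... passed on to methods
#' @return a `faers_cases` object: list of tibbles `demo` (one row per
#'   case), `drugs`, `reactions`, `indications`, `outcomes`
#' @export
deduplicate <- function(x, ...) UseMethod("deduplicate")

#' @rdname deduplicate
#' @param route_map,reporter_map,country_map normalization lookups; default
#'   to the bundled dictionaries
#' @export
deduplicate.faers_raw <- function(x,
                                  route_map = load_route_map(),
                                  reporter_map = load_reporter_map(),
                                  country_map = load_country_map(), ...) {
  demo <- x$demo
  if (nrow(demo) == 0L) {
    return(empty_faers_cases())
  }
  demo$caseversion_n <- num_or_na(demo$caseversion)
  demo$caseversion_n[is.na(demo$caseversion_n)] <- 0
  demo$primaryid_n <- num_or_na(demo$primaryid)
  ord <- order(demo$caseid, -demo$caseversion_n, -demo$primaryid_n)
  demo <- demo[ord, , drop = FALSE]
  keep <- !duplicated(demo$caseid)
  demo <- demo[keep, , drop = FALSE]
  kept_pid <- demo$primaryid

  pid_to_case <- stats::setNames(demo$caseid, demo$primaryid)
  child <- function(tb) {
    d <- x[[tb]][x[[tb]]$primaryid %in% kept_pid, , drop = FALSE]
    d$case_id <- unname(pid_to_case[d$primaryid])
    d
  }

  drug <- child("drug")
  reac <- child("reac")
  indi <- child("indi")
  outc <- child("outc")

  routes_raw <- toupper(trimws(drug$route))
  route <- unname(route_map[routes_raw])
  unmapped <- is.na(route) & routes_raw != ""
  if (any(unmapped)) {
    warning(sum(unmapped), " drug route value(s) not in the route map; ",
            "treated as unknown", call. = FALSE)
  }
  route[is.na(route)] <- "unknown"

  role <- unname(role_map[toupper(trimws(drug$role_cod))])
  role[is.na(role)] <- "concomitant"

  reporter <- unname(reporter_map[toupper(trimws(demo$occp_cod))])
  reporter[is.na(reporter)] <- "unknown"

  country <- unname(country_map[toupper(trimws(demo$reporter_country))])
  country[is.na(country)] <- "other"

  sex <- c(F = "female", M = "male")[toupper(trimws(demo$sex))]
  sex[is.na(sex)] <- "unknown"

  age_years <- harmonize_age_years(demo$age, demo$age_cod)

  demo_out <- tibble::tibble(
    case_id = demo$caseid,
    primaryid = demo$primaryid,
    caseversion = demo$caseversion_n,
    received_date = parse_event_date(demo$event_dt),
    age_years = age_years,
    age_band = age_band(age_years),
    sex = unname(sex),
    weight_kg = harmonize_weight_kg(demo$wt, demo$wt_cod),
    reporter = reporter,
    country_group = country
  )

  drugs_out <- tibble::tibble(
    case_id = drug$case_id,
    drug_seq = num_or_na(drug$drug_seq),
    name_raw = drug$drugname,
    active_ingredient = drug$prod_ai,
    role = role,
    route = route
  )

  reactions_out <- tibble::tibble(
    case_id = reac$case_id,
    pt = canonical_pt(reac$pt)
  )
  reactions_out <- reactions_out[!is.na(reactions_out$pt), , drop = FALSE]

  indications_out <- tibble::tibble(
    case_id = indi$case_id,
    drug_seq = num_or_na(indi$indi_drug_seq),
    pt = canonical_pt(indi$indi_pt)
  )
  indications_out <- indications_out[!is.na(indications_out$pt), , drop = FALSE]

  outcome <- unname(outcome_map[toupper(trimws(outc$outc_cod))])
  outcomes_out <- tibble::tibble(case_id = outc$case_id, outcome = outcome)
  outcomes_out <- outcomes_out[!is.na(outcomes_out$outcome), , drop = FALSE]
  outcomes_out <- dplyr::distinct(outcomes_out)

  # a safety report must carry at least one reaction
  has_reac <- demo_out$case_id %in% reactions_out$case_id
  if (any(!has_reac)) {
    message("deduplicate: dropped ", sum(!has_reac),
            " case(s) with no reaction terms")
  }
  out <- new_faers_cases(demo_out[has_reac, , drop = FALSE], drugs_out,
                         reactions_out, indications_out, outcomes_out)
  subset_cases(out, out$demo$case_id)
}

#' @rdname deduplicate
#' @export
deduplicate.faers_cases <- function(x, ...) {
  keep_ids <- x$demo$case_id[!duplicated(x$demo$case_id)]
  if (length(keep_ids) == nrow(x$demo)) return(x)
  subset_cases(x, keep_ids)
}

new_faers_cases <- function(demo, drugs, reactions, indications, outcomes) {
  structure(list(demo = demo, drugs = drugs, reactions = reactions,
                 indications = indications, outcomes = outcomes),
            class = "faers_cases")
}

empty_faers_cases <- function() {
  new_faers_cases(
    demo = tibble::tibble(case_id = character(), primaryid = character(),
                          caseversion = numeric(),
                          received_date = as.Date(character()),
                          age_years = numeric(), age_band = character(),
                          sex = character(), weight_kg = numeric(),
                          reporter = character(), country_group = character()),
    drugs = tibble::tibble(case_id = character(), drug_seq = numeric(),
                           name_raw = character(),
                           active_ingredient = character(),
                           role = character(), route = character()),
    reactions = tibble::tibble(case_id = character(), pt = character()),
    indications = tibble::tibble(case_id = character(), drug_seq = numeric(),
                                 pt = character()),
    outcomes = tibble::tibble(case_id = character(), outcome = character())
  )
}

#' Number of cases in a case set
#'
#' @param x a `faers_cases` object
#' @return integer count of unique cases
#' @export
n_cases <- function(x) nrow(x$demo)

#' Subset a case set by case identifiers
#'
#' Children tables are filtered consistently.
#'
#' @param x a `faers_cases` object
#' @param case_ids character vector of case identifiers to keep
#' @return a `faers_cases` object
#' @export
subset_cases <- function(x, case_ids) {
  new_faers_cases(
    demo = x$demo[x$demo$case_id %in% case_ids, , drop = FALSE],
    drugs = x$drugs[x$drugs$case_id %in% case_ids, , drop = FALSE],
    reactions = x$reactions[x$reactions$case_id %in% case_ids, , drop = FALSE],
    indications = x$indications[x$indications$case_id %in% case_ids, ,
                                drop = FALSE],
    outcomes = x$outcomes[x$outcomes$case_id %in% case_ids, , drop = FALSE]
  )
}

#' @export
print.faers_cases <- function(x, ...) {
  cat(sprintf("<faers_cases> %d cases, %d drug rows, %d reactions\n",
              n_cases(x), nrow(x$drugs), nrow(x$reactions)))
  invisible(x)
}

#' Write raw tables as one FAERS-dialect quarter
#'
#' Emits the six dollar-delimited ASCII files (`DEMOyyQq.txt`, ...) that
#' [read_quarter()] reads back.
#'
#' @param raw a `faers_raw` object
#' @param dir output directory (created if absent)
#' @param quarter quarter label used in the file stems, e.g. `"24Q1"`
#' @return named character vector of the written paths, invisibly
#' @export
write_quarter <- function(raw, dir, quarter = "24Q1") {
  stopifnot(inherits(raw, "faers_raw"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stems <- c(demo = "DEMO", drug = "DRUG", reac = "REAC",
             indi = "INDI", outc = "OUTC", rpsr = "RPSR")
  paths <- character(0)
  for (tb in names(stems)) {
    p <- file.path(dir, paste0(stems[[tb]], quarter, ".txt"))
    d <- as.data.frame(raw[[tb]])
    utils::write.table(d, p, sep = "$", quote = FALSE, row.names = FALSE,
                       col.names = TRUE, fileEncoding = "UTF-8", eol = "\n",
                       na = "")
    paths[tb] <- p
  }
  invisible(paths)
}

# serialization for the normalized single-file case store: one row per case,
# child records joined with "|" and child fields with ";". These two
# characters are reserved and replaced by "," on write.
store_clean <- function(x) gsub("[|;]", ",", ifelse(is.na(x), "", x))

#' Write a deduplicated case set to a single-file case store
#'
#' One row per case; nested children (drugs, reactions, indications,
#' outcomes) serialized in delimited sub-fields (records joined by `|`,
#' fields within a drug record by `;` as `name;ingredient;role;route;seq`).
#' `|` and `;` inside values are replaced by `,`.
#'
#' @param cases a `faers_cases` object
#' @param path output file (tab-separated)
#' @return `path`, invisibly
#' @export
write_case_store <- function(cases, path) {
  pack <- function(tb, id, fields) {
    if (nrow(tb) == 0L) return(stats::setNames(character(0), character(0)))
    rec <- do.call(paste, c(lapply(fields, function(f) store_clean(tb[[f]])),
                            sep = ";"))
    vapply(split(rec, tb[[id]]), paste, character(1), collapse = "|")
  }
  d <- cases$demo
  dr <- pack(cases$drugs, "case_id",
             c("name_raw", "active_ingredient", "role", "route", "drug_seq"))
  re <- pack(cases$reactions, "case_id", "pt")
  ind <- pack(cases$indications, "case_id", c("drug_seq", "pt"))
  ou <- pack(cases$outcomes, "case_id", "outcome")
  get <- function(v) unname(ifelse(is.na(v[d$case_id]), "", v[d$case_id]))
  out <- data.frame(d, drugs = get(dr), reactions = get(re),
                    indications = get(ind), outcomes = get(ou),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read a single-file case store written by [write_case_store()]
#'
#' @param path path to the store file
#' @return a `faers_cases` object
#' @export
read_case_store <- function(path) {
  d <- utils::read.delim(path, sep = "\t", quote = "",
                         colClasses = "character", check.names = FALSE,
                         stringsAsFactors = FALSE)
  unpack <- function(col, fields) {
    keep <- d[[col]] != ""
    ids <- d$case_id[keep]
    recs <- strsplit(d[[col]][keep], "|", fixed = TRUE)
    ids_long <- rep(ids, lengths(recs))
    parts <- strsplit(unlist(recs), ";", fixed = TRUE)
    out <- lapply(seq_along(fields), function(i) {
      vapply(parts, function(p) if (length(p) >= i) p[[i]] else "",
             character(1))
    })
    names(out) <- fields
    tibble::as_tibble(c(list(case_id = ids_long), out))
  }
  drugs <- unpack("drugs",
                  c("name_raw", "active_ingredient", "role", "route",
                    "drug_seq"))
  drugs$drug_seq <- num_or_na(drugs$drug_seq)
  drugs <- drugs[, c("case_id", "drug_seq", "name_raw",
                     "active_ingredient", "role", "route")]
  reactions <- unpack("reactions", "pt")
  indications <- unpack("indications", c("drug_seq", "pt"))
  indications$drug_seq <- num_or_na(indications$drug_seq)
  indications <- indications[, c("case_id", "drug_seq", "pt")]
  outcomes <- unpack("outcomes", "outcome")
  demo <- tibble::tibble(
    case_id = d$case_id, primaryid = d$primaryid,
    caseversion = num_or_na(d$caseversion),
    received_date = as.Date(d$received_date),
    age_years = num_or_na(d$age_years), age_band = d$age_band,
    sex = d$sex, weight_kg = num_or_na(d$weight_kg),
    reporter = d$reporter, country_group = d$country_group
  )
  new_faers_cases(demo, drugs, reactions, indications, outcomes)
}
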