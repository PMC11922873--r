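# in-code fixtures: tiny FAERS-dialect raw tables built row by row

demo_row <- function(primaryid, caseid, caseversion = "1",
                     event_dt = "20200101", age = "70", age_cod = "YR",
                     sex = "M", wt = "70", wt_cod = "KG",
                     reporter_country = "US", occp_cod = "MD") {
  tibble::tibble(primaryid = primaryid, caseid = caseid,
                 caseversion = caseversion, event_dt = event_dt, age = age,
                 age_cod = age_cod, sex = sex, wt = wt, wt_cod = wt_cod,
                 reporter_country = reporter_country, occp_cod = occp_cod)
}

drug_row <- function(primaryid, caseid, drug_seq = "1", role_cod = "PS",
                     drugname = "MADOPAR",
                     prod_ai = "LEVODOPA\\BENSERAZIDE", route = "ORAL") {
  tibble::tibble(primaryid = primaryid, caseid = caseid,
                 drug_seq = drug_seq, role_cod = role_cod,
                 drugname = drugname, prod_ai = prod_ai, route = route)
}

reac_row <- function(primaryid, caseid, pt) {
  tibble::tibble(primaryid = primaryid, caseid = caseid, pt = pt)
}

indi_row <- function(primaryid, caseid, indi_drug_seq = "1",
                     indi_pt = "Parkinson's disease") {
  tibble::tibble(primaryid = primaryid, caseid = caseid,
                 indi_drug_seq = indi_drug_seq, indi_pt = indi_pt)
}

outc_row <- function(primaryid, caseid, outc_cod = "HO") {
  tibble::tibble(primaryid = primaryid, caseid = caseid,
                 outc_cod = outc_cod)
}

empty_tab <- function(cols) {
  tibble::as_tibble(stats::setNames(
    as.data.frame(matrix(character(0), 0, length(cols))), cols))
}

make_raw <- function(demo, drug = NULL, reac = NULL, indi = NULL,
                     outc = NULL, rpsr = NULL) {
  structure(list(
    demo = demo,
    drug = drug %||% empty_tab(c("primaryid", "caseid", "drug_seq",
                                 "role_cod", "drugname", "prod_ai",
                                 "route")),
    reac = reac %||% empty_tab(c("primaryid", "caseid", "pt")),
    indi = indi %||% empty_tab(c("primaryid", "caseid", "indi_drug_seq",
                                 "indi_pt")),
    outc = outc %||% empty_tab(c("primaryid", "caseid", "outc_cod")),
    rpsr = rpsr %||% empty_tab(c("primaryid", "caseid", "rpsr_cod"))
  ), class = "faers_raw", rejects = list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one fully screened-in case: suspect levodopa/benserazide, oral, PD
# indication, a whitelisted-SOC reaction
eligible_case <- function(caseid, pid = paste0(caseid, "1"),
                          pt = "Dyskinesia", sex = "M") {
  list(demo = demo_row(pid, caseid, sex = sex),
       drug = drug_row(pid, caseid),
       reac = reac_row(pid, caseid, pt),
       indi = indi_row(pid, caseid))
}

bind_raw <- function(cases) {
  make_raw(
    demo = dplyr::bind_rows(lapply(cases, `[[`, "demo")),
    drug = dplyr::bind_rows(lapply(cases, `[[`, "drug")),
    reac = dplyr::bind_rows(lapply(cases, `[[`, "reac")),
    indi = dplyr::bind_rows(lapply(cases, `[[`, "indi"))
  )
}
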