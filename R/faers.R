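## Ingestion of FAERS-style quarterly `$`-delimited tables: DRUG x REAC
## cross product per Individual Safety Report (ISR), demographic enrichment,
## duplicate elimination on (ISR, case-id, follow-up code, drug, event) with
## initial and follow-up reports kept as distinct instances, dictionary
## normalization, and per-window contingency counts.

#' Default FAERS column mapping
#'
#' Maps the package's field names onto the column headers of public FAERS
#' ASCII exports.  Override individual entries for other dialects.
#'
#' @param ... named overrides, e.g. `isr = "primaryid"`.
#' @return named list.
#' @export
faers_colmap <- function(...) {
  m <- list(isr = "ISR", case_id = "CASE", fu_code = "I_F_COD",
            drug_name = "DRUGNAME", reaction_pt = "PT",
            event_date = "EVENT_DT", report_date = "FDA_DT",
            age = "AGE", gender = "GNDR_COD")
  utils::modifyList(m, list(...))
}

read_dollar_table <- function(path, need, colmap) {
  if (!file.exists(path)) stopf("read_faers_quarter: no such file '%s'", path)
  dt <- data.table::fread(path, sep = "$", header = TRUE, quote = "",
                          colClasses = "character", encoding = "UTF-8",
                          fill = TRUE)
  cols <- unlist(colmap[need], use.names = TRUE)
  missing <- setdiff(unname(cols), names(dt))
  if (length(missing))
    stopf("read_faers_quarter: '%s' lacks column(s) %s", path,
          paste(missing, collapse = ", "))
  out <- dt[, unname(cols), with = FALSE]
  data.table::setnames(out, names(cols))
  out
}

## yyyymmdd (FAERS) or ISO; anything else becomes NA
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  num <- !is.na(x) & grepl("^\\d{8}$", x)
  out[num] <- as.Date(x[num], format = "%Y%m%d")
  iso <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[iso] <- as.Date(x[iso], format = "%Y-%m-%d")
  out
}

#' Read one FAERS-style quarter
#'
#' Joins the `$`-delimited DRUG and REAC tables on ISR (cross product of a
#' report's drug rows and reaction rows) and enriches each pair with the
#' DEMO table's case id, initial/follow-up code and dates.  Pairs whose ISR
#' is absent from DEMO are dropped with a warning.
#'
#' @param drug_path,reac_path,demo_path file paths.
#' @param colmap a [faers_colmap()].
#' @return data.table of report records: `isr`, `case_id`, `fu_code`
#'   ("initial"/"followup"), `drug_name`, `reaction_pt`, `event_date`,
#'   `report_date`, `age`, `gender`.
#' @export
read_faers_quarter <- function(drug_path, reac_path, demo_path,
                               colmap = faers_colmap()) {
  drug <- read_dollar_table(drug_path, c("isr", "drug_name"), colmap)
  reac <- read_dollar_table(reac_path, c("isr", "reaction_pt"), colmap)
  demo <- read_dollar_table(demo_path,
                            c("isr", "case_id", "fu_code", "event_date",
                              "report_date", "age", "gender"), colmap)
  if (any(!nzchar(trimws(drug$isr))))
    stopf("read_faers_quarter: empty ISR at line %d of '%s'",
          which(!nzchar(trimws(drug$isr)))[1] + 1L, drug_path)
  if (any(!nzchar(trimws(reac$isr))))
    stopf("read_faers_quarter: empty ISR at line %d of '%s'",
          which(!nzchar(trimws(reac$isr)))[1] + 1L, reac_path)
  pairs <- merge(drug, reac, by = "isr", allow.cartesian = TRUE)
  known <- pairs$isr %in% demo$isr
  if (any(!known))
    warnf("read_faers_quarter: dropping %d drug-reaction pair(s) whose ISR is absent from DEMO",
          sum(!known))
  pairs <- pairs[known]
  out <- merge(pairs, demo, by = "isr")
  fu <- toupper(substr(trimws(out$fu_code), 1, 1))
  fu[!nzchar(fu) | fu == "I"] <- "initial"
  fu[fu == "F"] <- "followup"
  bad <- !fu %in% c("initial", "followup")
  if (any(bad))
    stopf("read_faers_quarter: unrecognized follow-up code '%s'",
          out$fu_code[bad][1])
  out[, fu_code := fu]
  out[, event_date := parse_faers_date(event_date)]
  out[, report_date := parse_faers_date(report_date)]
  out[order(isr, drug_name, reaction_pt),
      .(isr, case_id, fu_code, drug_name, reaction_pt, event_date,
        report_date, age, gender)]
}

#' Eliminate duplicate report rows
#'
#' Collapses exact duplicates of the tuple (ISR, case id, follow-up code,
#' drug, event) to one instance; an initial and a follow-up report of the
#' same case remain two distinct instances.  Row order of the input is
#' irrelevant; the output is sorted on the key.
#'
#' @param records output of [read_faers_quarter()] (possibly several
#'   quarters rbound together).
#' @return data.table of unique pair instances: `isr`, `case_id`,
#'   `fu_code`, `drug`, `event`, `event_date`, `report_date`.
#' @export
dedupe_reports <- function(records) {
  rec <- as.data.table(records)
  if (nrow(rec) == 0)
    return(data.table(isr = character(), case_id = character(),
                      fu_code = character(), drug = character(),
                      event = character(), event_date = as.Date(character()),
                      report_date = as.Date(character())))
  out <- rec[, .(event_date = suppressWarnings(min(event_date, na.rm = TRUE)),
                 report_date = suppressWarnings(min(report_date, na.rm = TRUE))),
             by = .(isr, case_id, fu_code, drug = drug_name,
                    event = reaction_pt)]
  out[is.infinite(as.numeric(event_date)), event_date := as.Date(NA)]
  out[is.infinite(as.numeric(report_date)), report_date := as.Date(NA)]
  out[order(isr, case_id, fu_code, drug, event)]
}

#' Normalize deduplicated instances against the dictionaries
#'
#' Drug and event surfaces are matched exactly (after case/whitespace
#' normalization) against the drug and event dictionaries; a hit replaces
#' the surface by the concept's canonical term, a miss keeps the lower-cased
#' surface as-is.
#'
#' @param instances output of [dedupe_reports()].
#' @param drugs,events dictionaries.
#' @return `instances` with `drug`, `event` replaced by canonical terms and
#'   extra columns `drug_concept`, `drug_in_dict`, `event_concept`,
#'   `event_in_dict`.
#' @export
normalize_records <- function(instances, drugs, events) {
  inst <- data.table::copy(as.data.table(instances))
  if (nrow(inst) == 0) {
    inst[, `:=`(drug_concept = character(), drug_in_dict = logical(),
                event_concept = character(), event_in_dict = logical())]
    return(inst)
  }
  nd <- normalize_terms(drugs, inst$drug)
  ne <- normalize_terms(events, inst$event)
  inst[, `:=`(drug = nd$canonical,
              drug_concept = ifelse(nd$in_dict, nd$concept_id, nd$canonical),
              drug_in_dict = nd$in_dict,
              event = ne$canonical,
              event_concept = ifelse(ne$in_dict, ne$concept_id, ne$canonical),
              event_in_dict = ne$in_dict)]
  inst
}

#' Contingency counts from FAERS pair instances
#'
#' A "document" is one report instance, identified by (ISR, case id,
#' follow-up code).  Instances are first restricted to those whose FDA
#' report date falls inside the window (undated instances count only in the
#' unbounded window).  With `drug`/`event` given, returns the single pair's
#' counts; otherwise the full table of pairs present in the window.
#'
#' @param instances output of [normalize_records()] (or [dedupe_reports()]).
#' @param window a [time_window()]; default unbounded.
#' @param drug,event optional canonical terms selecting one pair.
#' @return one `pv_contingency` (single pair) or a data.table
#'   (`drug`, `event`, `c_x`, `c_y`, `c_xy`, `n`).
#' @export
faers_contingency <- function(instances, window = time_window("complete"),
                              drug = NULL, event = NULL) {
  inst <- as.data.table(instances)
  if (nrow(inst)) {
    if (!is_unbounded(window)) {
      keep <- !is.na(inst$report_date)
      if (!is.null(window$start)) keep <- keep & inst$report_date >= window$start
      if (!is.null(window$end)) keep <- keep & inst$report_date <= window$end
      inst <- inst[keep]
    }
  }
  single <- !is.null(drug) && !is.null(event)
  if (nrow(inst) == 0) {
    if (single)
      return(structure(list(c_x = 0L, c_y = 0L, c_xy = 0L, n = 0L),
                       class = "pv_contingency"))
    return(data.table(drug = character(), event = character(),
                      c_x = integer(), c_y = integer(), c_xy = integer(),
                      n = integer()))
  }
  inst[, report_id := paste(isr, case_id, fu_code, sep = "\r")]
  n <- data.table::uniqueN(inst$report_id)
  if (single) {
    drug_sel <- drug; event_sel <- event
    rx <- unique(inst$report_id[inst$drug == drug_sel])
    ry <- unique(inst$report_id[inst$event == event_sel])
    return(structure(list(c_x = length(rx), c_y = length(ry),
                          c_xy = length(intersect(rx, ry)), n = n),
                     class = "pv_contingency"))
  }
  dd <- unique(inst[, .(report_id, drug)])
  de <- unique(inst[, .(report_id, event)])
  joint <- unique(inst[, .(report_id, drug, event)])[
    , .(c_xy = .N), by = .(drug, event)]
  nx <- dd[, .(c_x = .N), by = drug]
  ny <- de[, .(c_y = .N), by = event]
  out <- merge(joint, nx, by = "drug", allow.cartesian = TRUE)
  out <- merge(out, ny, by = "event", allow.cartesian = TRUE)
  out[, n := n]
  out[order(drug, event), .(drug, event, c_x, c_y, c_xy, n)]
}
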