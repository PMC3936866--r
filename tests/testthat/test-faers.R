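## toy $-delimited quarter built in code
write_quarter <- function(drug_rows, reac_rows, demo_rows) {
  list(drug = write_lines_tmp(c("ISR$DRUG_SEQ$DRUGNAME", drug_rows)),
       reac = write_lines_tmp(c("ISR$PT", reac_rows)),
       demo = write_lines_tmp(
         c("ISR$CASE$I_F_COD$EVENT_DT$FDA_DT$AGE$GNDR_COD", demo_rows)))
}

test_that("drug x reaction rows cross-join on ISR with demographics", {
  q <- write_quarter(
    drug_rows = c("1$1$WELLBUTRIN", "1$2$ASPIRIN"),
    reac_rows = c("1$DRY MOUTH", "1$SEIZURES"),
    demo_rows = "1$C1$I$20090102$20090301$44$F")
  rec <- read_faers_quarter(q$drug, q$reac, q$demo)
  expect_equal(nrow(rec), 4L)  # 2 drugs x 2 reactions
  expect_setequal(rec$drug_name, c("WELLBUTRIN", "ASPIRIN"))
  expect_identical(unique(rec$case_id), "C1")
  expect_identical(unique(rec$fu_code), "initial")
  expect_identical(unique(rec$report_date), as.Date("2009-03-01"))
})

test_that("pairs with ISR missing from DEMO are dropped with a warning", {
  q <- write_quarter(
    drug_rows = c("1$1$ASPIRIN", "2$1$WARFARIN"),
    reac_rows = c("1$NAUSEA", "2$RASH"),
    demo_rows = "1$C1$I$20090101$20090101$50$M")
  expect_warning(rec <- read_faers_quarter(q$drug, q$reac, q$demo),
                 "absent from DEMO")
  expect_equal(nrow(rec), 1L)
  expect_identical(rec$drug_name, "ASPIRIN")
  ## empty tables give an empty record set
  q0 <- write_quarter(character(), character(), character())
  expect_equal(nrow(read_faers_quarter(q0$drug, q0$reac, q0$demo)), 0L)
})

test_that("deduplication collapses exact duplicates but keeps follow-ups", {
  rec <- data.table::data.table(
    isr = c("1", "1", "2"), case_id = c("C1", "C1", "C1"),
    fu_code = c("initial", "initial", "followup"),
    drug_name = "ASPIRIN", reaction_pt = "NAUSEA",
    event_date = as.Date("2009-01-01"), report_date = as.Date("2009-02-01"),
    age = "50", gender = "F")
  inst <- dedupe_reports(rec)
  ## two identical initial rows collapse; the follow-up stays separate
  expect_equal(nrow(inst), 2L)
  expect_setequal(inst$fu_code, c("initial", "followup"))
  ## idempotent and never growing
  renamed <- data.table::copy(inst)
  data.table::setnames(renamed, c("drug", "event"),
                       c("drug_name", "reaction_pt"))
  expect_equal(nrow(dedupe_reports(renamed)), nrow(inst))
  expect_equal(nrow(dedupe_reports(rec[0])), 0L)
})

test_that("dedup and counting are invariant to input row order", {
  set.seed(11)
  rec <- data.table::data.table(
    isr = as.character(rep(1:6, each = 2)),
    case_id = paste0("C", rep(1:3, each = 4)),
    fu_code = rep(c("initial", "followup"), 6),
    drug_name = sample(c("ASPIRIN", "WARFARIN"), 12, TRUE),
    reaction_pt = sample(c("NAUSEA", "RASH"), 12, TRUE),
    event_date = as.Date("2009-01-01"), report_date = as.Date("2009-02-01"),
    age = "50", gender = "F")
  rec_dup <- rbind(rec, rec[c(3, 1, 7)])  # inject exact duplicates
  a <- dedupe_reports(rec_dup)
  b <- dedupe_reports(rec_dup[sample(nrow(rec_dup))])
  expect_identical(a, b)
  expect_identical(faers_contingency(a), faers_contingency(b))
})

test_that("record normalization maps hits to canonical terms, keeps misses", {
  inst <- data.table::data.table(
    isr = c("1", "2"), case_id = c("C1", "C2"), fu_code = "initial",
    drug = c("WELLBUTRIN", "ASPIRIN"),
    event = c("TARDIVE DYSKINESIA", "DRY MOUTH"),
    event_date = as.Date(NA), report_date = as.Date("2009-01-01"))
  out <- normalize_records(inst, toy_drug_dict(), toy_event_dict())
  expect_identical(out$drug, c("bupropion", "aspirin"))
  expect_identical(out$event, c("tardive dyskinesia", "dry mouth"))
  expect_identical(out$event_in_dict, c(FALSE, TRUE))
  ## already-canonical input is unchanged
  out2 <- normalize_records(out, toy_drug_dict(), toy_event_dict())
  expect_identical(out2$drug, out$drug)
  expect_identical(out2$event, out$event)
})

test_that("faers contingency counts report instances within the window", {
  inst <- data.table::data.table(
    isr = c("1", "1", "2", "2", "3", "3"),
    case_id = paste0("C", c(1, 1, 2, 2, 3, 3)), fu_code = "initial",
    drug = c("d", "d", "d", "d", "e", "e"),
    event = c("x", "x2", "y", "y2", "x", "x2"),
    event_date = as.Date(NA),
    report_date = as.Date(c("2009-01-01", "2009-01-01", "2009-06-01",
                            "2009-06-01", "2011-01-01", "2011-01-01")))
  ## 3 reports: {d,x}, {d,y}, {e,x} (plus extra events to test sets)
  ct <- faers_contingency(inst, drug = "d", event = "x")
  expect_equal(ct$c_x, 2L)
  expect_equal(ct$c_y, 2L)
  expect_equal(ct$c_xy, 1L)
  expect_equal(ct$n, 3L)
  ## bounded window drops the 2011 report
  w1 <- time_window("w1", "2008-01-01", "2009-12-31")
  ct_w <- faers_contingency(inst, w1, drug = "d", event = "x")
  expect_equal(ct_w$c_y, 1L)
  expect_equal(ct_w$n, 2L)
  ## a window excluding everything gives all zeros
  w_none <- time_window("none", "1990-01-01", "1990-12-31")
  ct0 <- faers_contingency(inst, w_none, drug = "d", event = "x")
  expect_equal(unlist(unclass(ct0)), c(c_x = 0L, c_y = 0L, c_xy = 0L, n = 0L))
  ## full table satisfies the contingency inequalities
  tab <- faers_contingency(inst)
  expect_true(all(tab$c_xy <= pmin(tab$c_x, tab$c_y)))
  expect_true(all(pmax(tab$c_x, tab$c_y) <= tab$n))
})
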