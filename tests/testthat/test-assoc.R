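## helper: annotations with k mentions of one concept in one document
mk_ann <- function(doc, cid, cls, k = 1L) {
  data.table::data.table(doc_id = doc, field = "body",
                         start = seq_len(k) - 1L, end = seq_len(k),
                         concept_id = cid, entity_class = cls, surface = cid)
}

## hand-worked corpus: total frequency N = 10; t1 has 2 mentions
## in A(e) and 4 overall; t2 has 1 mention in A(e) and 1 overall
handworked_counts <- function() {
  ann <- rbind(mk_ann("d1", "e", "drug", 1),
               mk_ann("d1", "t1", "event", 2),
               mk_ann("d2", "t1", "event", 2),
               mk_ann("d1", "t2", "event", 1),
               mk_ann("d3", "z", "event", 4))
  count_entities(ann, c("d1", "d2", "d3", "d4"))
}

test_that("count_entities separates mention frequencies from document sets", {
  cnt <- count_entities(rbind(mk_ann("d1", "X", "event", 2)), c("d1", "d2"))
  expect_equal(unname(cnt$freq_total["X"]), 2)
  expect_equal(nrow(cnt$doc_concept), 1L)
  cnt2 <- count_entities(rbind(mk_ann("d1", "X", "event", 1),
                               mk_ann("d2", "X", "event", 1)), c("d1", "d2"))
  expect_equal(unname(cnt2$freq_total["X"]), 2)
  expect_equal(cnt2$doc_concept[concept_id == "X", .N], 2L)
  empty <- count_entities(mk_ann("d", "x", "event", 0)[0], c("d1"))
  expect_equal(empty$total_freq, 0)
  expect_error(count_entities(mk_ann("zz", "X", "event", 1), c("d1")),
               "unknown doc_id")
})

test_that("association score reproduces the hand-worked tf-idf value", {
  cnt <- handworked_counts()
  expect_equal(cnt$total_freq, 10)
  s <- association_score(cnt, "e", "t1")
  expect_equal(s$b_score, 2 * log(11 / 4))
  expect_equal(s$p_score, 2 * log(11 / 4) / (2 * log(11 / 4) + log(11)),
               tolerance = 1e-12)
  ## error (not zero) for a non-co-occurring pair
  expect_error(association_score(cnt, "e", "z"), "does not co-occur")
})

test_that("P sums to one per drug and is invariant to the log base", {
  for (seed in 1:5) {
    cnt <- with(new.env(), {
      set.seed(seed)
      docs <- paste0("d", 1:12)
      ann <- data.table::rbindlist(lapply(docs, function(d) {
        drugs <- sample(c("A", "B"), sample(0:2, 1))
        events <- sample(c("u", "v", "w", "x"), sample(1:3, 1))
        data.table::rbindlist(c(
          lapply(drugs, function(g) mk_ann(d, g, "drug", sample(1:3, 1))),
          lapply(events, function(g) mk_ann(d, g, "event", sample(1:2, 1)))))
      }))
      count_entities(ann, docs)
    })
    for (e in intersect(c("A", "B"), names(cnt$freq_total))) {
      tab <- pvsignal:::assoc_b_table(cnt, e)
      expect_equal(sum(tab$B / sum(tab$B)), 1, tolerance = 1e-9)
      ## every B is non-negative (N + 1 > N(t, A) always)
      expect_true(all(tab$B >= 0))
      for (t in tab$concept_id) {
        p_e <- association_score(cnt, e, t, base = exp(1))$p_score
        p_2 <- association_score(cnt, e, t, base = 2)$p_score
        p_10 <- association_score(cnt, e, t, base = 10)$p_score
        expect_equal(p_e, p_2, tolerance = 1e-12)
        expect_equal(p_e, p_10, tolerance = 1e-12)
      }
    }
  }
})

test_that("pair table lists co-occurring drug-event pairs only", {
  cnt <- handworked_counts()
  pairs <- build_pair_table(cnt)
  expect_setequal(pairs$event, c("t1", "t2"))  # z never co-occurs with e
  expect_equal(pairs[event == "t1", n_docs_together], 1L)
  expect_equal(sum(pairs$p_score), 1, tolerance = 1e-12)
  ## symmetric corpus: identical counts give equal p_scores
  ann <- rbind(mk_ann("d1", "D", "drug"), mk_ann("d1", "x", "event"),
               mk_ann("d1", "y", "event"))
  sym <- build_pair_table(count_entities(ann, "d1"))
  expect_equal(sym$p_score[1], sym$p_score[2])
})

test_that("pair_contingency counts documents, not mentions", {
  ## drug in docs {1,2}, event in {2,3}, 4 docs
  ann <- rbind(mk_ann("d1", "D", "drug", 3), mk_ann("d2", "D", "drug"),
               mk_ann("d2", "X", "event", 2), mk_ann("d3", "X", "event"))
  cnt <- count_entities(ann, paste0("d", 1:4))
  ct <- pair_contingency(cnt, "D", "X")
  expect_equal(ct$c_x, 2L)
  expect_equal(ct$c_y, 2L)
  expect_equal(ct$c_xy, 1L)
  expect_equal(ct$n, 4L)
  expect_error(pair_contingency(cnt, "D", "nope"), "unknown concept")
})

test_that("contingency agrees with a brute-force set-intersection oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    docs <- paste0("d", 1:8)
    ann <- data.table::rbindlist(lapply(docs, function(d) {
      present <- sample(c("D1", "D2", "x", "y"), sample(0:4, 1))
      if (!length(present)) return(NULL)
      data.table::rbindlist(lapply(present, function(g)
        mk_ann(d, g, if (grepl("^D", g)) "drug" else "event",
               sample(1:2, 1))))
    }))
    if (is.null(ann) || nrow(ann) == 0) next
    cnt <- count_entities(ann, docs)
    ## oracle: direct set intersections over the raw annotations
    for (dr in intersect(c("D1", "D2"), ann$concept_id))
      for (ev in intersect(c("x", "y"), ann$concept_id)) {
        got <- pair_contingency(cnt, dr, ev)
        sx <- unique(ann[concept_id == dr, doc_id])
        sy <- unique(ann[concept_id == ev, doc_id])
        expect_equal(got$c_x, length(sx))
        expect_equal(got$c_y, length(sy))
        expect_equal(got$c_xy, length(intersect(sx, sy)))
        expect_true(got$c_xy <= min(got$c_x, got$c_y))
        expect_true(max(got$c_x, got$c_y) <= got$n)
      }
  }
})
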