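test_that("tokenizer produces offset-faithful word and punctuation tokens", {
  tok <- tokenize("dry mouth.")
  expect_identical(tok$text, c("dry", "mouth", "."))
  expect_identical(tok$start, c(0L, 4L, 9L))
  expect_identical(tok$end, c(3L, 9L, 10L))
  ## offsets reconstruct the input slices
  for (i in seq_len(nrow(tok)))
    expect_identical(substr("dry mouth.", tok$start[i] + 1, tok$end[i]),
                     tok$text[i])
  expect_equal(nrow(tokenize("")), 0L)
  expect_identical(tokenize("Tension-type (TTH)")$text,
                   c("Tension", "-", "type", "(", "TTH", ")"))
})

test_that("stems agree with the frozen reference Porter list", {
  gold <- data.table::fread(test_path("porter-gold.tsv"), header = FALSE,
                            col.names = c("word", "stem"))
  expect_gte(nrow(gold), 100L)
  expect_identical(porter_stem(gold$word), gold$stem)
})

test_that("sentence splitting respects parenthesized short forms", {
  expect_equal(nrow(split_sentences("A. B.")), 2L)
  expect_equal(nrow(split_sentences("x (A. E) y.")), 1L)
  expect_equal(nrow(split_sentences("")), 0L)
  s <- split_sentences("One sentence here. And another one.")
  expect_identical(
    substr("One sentence here. And another one.", s$start[1] + 1, s$end[1]),
    "One sentence here.")
  ## spans cover all non-whitespace text
  txt <- "  First bit! Second bit?  "
  s2 <- split_sentences(txt)
  covered <- paste(substring(txt, s2$start + 1, s2$end), collapse = " ")
  expect_identical(covered, "First bit! Second bit?")
})

test_that("acronym detection follows the short-form/long-form rules", {
  expect_identical(detect_acronyms("adverse event (AE) was noted"),
                   c(AE = "adverse event"))
  ## lowercase content in parentheses is not a short form
  expect_length(detect_acronyms("noted (see Figure)"), 0)
  ## first definition wins
  two <- detect_acronyms("adverse event (AE) and then another entry (AE).")
  expect_identical(two, c(AE = "adverse event"))
  ## long form must cover the letters in order
  expect_identical(
    detect_acronyms("the tension type headache (TTH) persisted"),
    c(TTH = "tension type headache"))
})

test_that("tagging finds drug and event mentions with correct classes", {
  doc <- list(doc_id = "d1", title = "",
              body = "bupropion caused dry mouth")
  ann <- tag_document(doc, toy_drug_dict(), toy_event_dict())
  expect_equal(nrow(ann), 2L)
  expect_identical(ann[entity_class == "drug", surface], "bupropion")
  expect_identical(ann[entity_class == "event", surface], "dry mouth")
  ## stemmed matching unifies surface variants, case-insensitively
  ann2 <- tag_document(list(doc_id = "d2", title = "",
                            body = "SEIZURES after Wellbutrin"),
                       toy_drug_dict(), toy_event_dict())
  expect_setequal(ann2$concept_id, c("seizure", "bupropion"))
  expect_equal(nrow(tag_document(list(doc_id = "d3", title = "", body = ""),
                                 toy_drug_dict(), toy_event_dict())), 0L)
})

test_that("acronyms defined in the body extend to title tagging", {
  doc <- list(doc_id = "d1", title = "AE incidence on warfarin.",
              body = "Each adverse event (AE) was recorded by staff.")
  ann <- tag_document(doc, toy_drug_dict(), toy_event_dict())
  title_ann <- ann[field == "title"]
  expect_setequal(title_ann$surface, c("AE", "warfarin"))
  expect_identical(title_ann[surface == "AE", concept_id], "adverse-event")
  expect_identical(title_ann[surface == "AE", entity_class], "event")
  ## without the body definition the title AE is not tagged
  ann2 <- tag_document(list(doc_id = "d2", title = "AE incidence.",
                            body = "Nothing defined here."),
                       toy_drug_dict(), toy_event_dict())
  expect_equal(nrow(ann2), 0L)
})

test_that("tagging is leftmost-longest, idempotent, and round-trips surfaces", {
  dicts <- list(d = toy_drug_dict(), e = toy_event_dict())
  texts <- c("dry mouth and seizures on acetylsalicylic acid",
             "a drowsy sleepy patient with nausea, nausea and dry mouth",
             "xerostomia. Convulsion! warfarin coumadin aspirin")
  for (tx in texts) {
    doc <- list(doc_id = "x", title = "", body = tx)
    ann <- tag_document(doc, dicts$d, dicts$e)
    ann2 <- tag_document(doc, dicts$d, dicts$e)
    expect_identical(ann, ann2)
    if (nrow(ann) > 1) {
      ## no annotation is a proper sub-span of another in the same field
      for (i in seq_len(nrow(ann)))
        for (j in seq_len(nrow(ann)))
          if (i != j && ann$field[i] == ann$field[j])
            expect_false(ann$start[i] >= ann$start[j] &&
                           ann$end[i] <= ann$end[j] &&
                           (ann$end[i] - ann$start[i] <
                              ann$end[j] - ann$start[j]))
    }
    for (i in seq_len(nrow(ann)))
      expect_identical(substr(tx, ann$start[i] + 1, ann$end[i]),
                       ann$surface[i])
  }
})

test_that("a document that is exactly one synonym yields exactly one annotation", {
  for (syn in c("bupropion", "zyban", "dry mouth", "xerostomia", "seizures")) {
    ann <- tag_document(list(doc_id = "x", title = "", body = syn),
                        toy_drug_dict(), toy_event_dict())
    expect_equal(nrow(ann), 1L)
    expect_identical(ann$surface, syn)
  }
})

test_that("drug matches take precedence over events on identical spans", {
  d <- dictionary(list(ambiguous = character()), "drug")
  e <- dictionary(list(ambiguous = character()), "event")
  ann <- tag_document(list(doc_id = "x", title = "", body = "ambiguous"),
                      d, e)
  expect_identical(ann$entity_class, "drug")
})
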