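## The six example sentences (deep agent / verb / deep patient; the last is
## the passivized form of "the surfer sees the musician")
example_sentences <- function() {
  list(sentence_from_gloss("surfer", "kick", "musician"),
       sentence_from_gloss("musician", "kick", "surfer"),
       sentence_from_gloss("musician", "kick", "pianist"),
       sentence_from_gloss("musician", "attack", "pianist"),
       sentence_from_gloss("surfer", "see", "pianist"),
       sentence_from_gloss("surfer", "see", "musician"))
}

test_that("predictor counts match the model definitions", {
  counts <- vapply(model_names(), predictor_count, integer(1))
  expect_equal(unname(counts), c(2L, 8L, 64L, 16L, 16L, 64L, 512L))
  expect_error(encoding_model("not_a_model"))
})

test_that("featurization reproduces the reference example rows bit-exactly", {
  sents <- example_sentences()
  bag <- t(vapply(sents, featurize, numeric(2), model = "bag_of_nouns_cat"))
  expect_identical(unname(bag),
                   matrix(c(1, 1,
                            1, 1,
                            1, 0,
                            1, 0,
                            1, 1,
                            1, 1), ncol = 2, byrow = TRUE))
  broad <- t(vapply(sents, featurize, numeric(8), model = "broad_roles"))
  cols <- c("M-as-agent", "M-as-patient", "A-as-agent", "A-as-patient",
            "M-as-experiencer", "M-as-stimulus", "A-as-experiencer",
            "A-as-stimulus")
  expect_identical(unname(broad[, cols]),
                   matrix(c(0, 1, 1, 0, 0, 0, 0, 0,
                            1, 0, 0, 1, 0, 0, 0, 0,
                            1, 1, 0, 0, 0, 0, 0, 0,
                            1, 1, 0, 0, 0, 0, 0, 0,
                            0, 0, 0, 0, 0, 1, 1, 0,
                            0, 0, 0, 0, 0, 1, 1, 0),
                          ncol = 8, byrow = TRUE))
  narrow <- t(vapply(sents, featurize, numeric(64), model = "narrow_roles"))
  kick_cols <- c("M-schoppen-subj", "M-schoppen-obj")   # M-as-kicker / kickee
  expect_identical(unname(narrow[, kick_cols]),
                   matrix(c(0, 1,
                            1, 0,
                            1, 1,
                            0, 0,
                            0, 0,
                            0, 0), ncol = 2, byrow = TRUE))
  ## noun-specific broad roles follow-up example
  ns <- featurize(sentence_from_gloss("violinist", "attack", "surfer"),
                  "noun_specific_broad_roles")
  expect_equal(sum(ns), 2)
  expect_equal(unname(ns[c("violist-as-agent", "surfer-as-patient")]), c(1, 1))
})

test_that("role assignment is voice-invariant and mirror-sensitive", {
  pool <- enumerate_pool(default_lexicon())
  set.seed(3)
  idx <- sample.int(nrow(pool), 25)
  for (m in model_names()) {
    spec <- encoding_model(m)
    for (i in idx) {
      s <- as.list(pool[i, ])
      active <- c(s, voice = "active")
      passive <- c(s, voice = "passive", passive_order = "verb_final")
      expect_identical(featurize(active, spec), featurize(passive, spec))
      mirror <- list(agent = s$patient, verb = s$verb, patient = s$agent)
      same <- identical(featurize(s, spec), featurize(mirror, spec))
      cat_lookup <- stats::setNames(default_lexicon()$category,
                                    default_lexicon()$lemma)
      same_cat <- cat_lookup[[s$agent]] == cat_lookup[[s$patient]]
      if (m %in% c("bag_of_nouns_cat", "bag_of_verbs",
                   "bag_of_nouns_specific")) {
        expect_true(same)          # bag models ignore role assignment
      } else if (m %in% c("broad_roles", "narrow_roles")) {
        ## category-level role models distinguish mirrors only across
        ## categories; same-category mirrors are identical by design
        expect_equal(same, same_cat)
      } else {
        expect_false(same)         # noun-specific role models always differ
      }
    }
  }
})

test_that("summing specific predictors within a category reproduces categorical columns", {
  sents <- cached_design(1)
  sents <- sents[sents$trial_type == "production", ][1:60, ]
  lex <- default_lexicon()
  music <- lex$lemma[lex$category == "music"]
  sport <- lex$lemma[lex$category == "sport"]

  broad <- build_design_matrix(sents, "broad_roles")
  nsb <- build_design_matrix(sents, "noun_specific_broad_roles")
  for (role in c("agent", "patient", "experiencer", "stimulus")) {
    expect_equal(unname(rowSums(nsb[, paste0(music, "-as-", role)])),
                 unname(broad[, paste0("M-as-", role)]))
    expect_equal(unname(rowSums(nsb[, paste0(sport, "-as-", role)])),
                 unname(broad[, paste0("A-as-", role)]))
  }
  narrow <- build_design_matrix(sents, "narrow_roles")
  full <- build_design_matrix(sents, "full_relational")
  verbs <- lex$lemma[lex$word_class == "verb"]
  for (v in verbs[c(1, 9)]) {
    expect_equal(unname(rowSums(full[, paste0(music, "-", v, "-subj")])),
                 unname(narrow[, paste0("M-", v, "-subj")]))
    expect_equal(unname(rowSums(full[, paste0(sport, "-", v, "-obj")])),
                 unname(narrow[, paste0("A-", v, "-obj")]))
  }
  ## categorical bag-of-nouns is the presence indicator of the specific one
  bag <- build_design_matrix(sents, "bag_of_nouns_cat")
  spec_bag <- build_design_matrix(sents, "bag_of_nouns_specific")
  expect_equal(unname(pmin(rowSums(spec_bag[, music]), 1)), unname(bag[, "M"]))
  expect_equal(unname(pmin(rowSums(spec_bag[, sport]), 1)), unname(bag[, "A"]))
})

test_that("design matrices have the documented shape and row sums", {
  sents <- cached_design(1)
  soi <- sents[sents$trial_type != "filler", ]
  X <- build_design_matrix(soi, "narrow_roles")
  expect_equal(dim(X), c(288L, 64L))
  expect_true(all(X %in% c(0, 1)))
  expect_true(all(rowSums(X) == 2))
  expect_true(all(rowSums(build_design_matrix(soi, "broad_roles")) == 2))
  expect_true(all(rowSums(build_design_matrix(soi, "bag_of_verbs")) == 1))
  expect_true(all(rowSums(build_design_matrix(soi, "bag_of_nouns_cat"))
                  %in% c(1, 2)))
  expect_error(build_design_matrix(soi, "narrow_roles",
                                   ids = rep(1, nrow(soi))),
               class = "id_collision")
  expect_error(featurize(list(agent = "zebra", verb = "zien",
                              patient = "surfer"), "broad_roles"),
               class = "unknown_item")
})
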