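## Shared fixtures, built in code. The full 288-sentence design is cached per
## seed because several files reuse it.
.design_cache <- new.env(parent = emptyenv())

cached_design <- function(seed = 1) {
  key <- paste0("design", seed)
  if (!exists(key, envir = .design_cache))
    assign(key, build_design(seed = seed), envir = .design_cache)
  get(key, envir = .design_cache)
}

## a tiny custom lexicon for degenerate/small cases
mini_lexicon <- function(nouns_sport = c("aa", "bbb"),
                         nouns_music = c("cccc", "ddddd"),
                         verbs_contact = c("kickit"),
                         verbs_perception = character(0)) {
  data.frame(
    lemma = c(nouns_sport, nouns_music, verbs_contact, verbs_perception),
    word_class = c(rep("noun", length(nouns_sport) + length(nouns_music)),
                   rep("verb", length(verbs_contact) + length(verbs_perception))),
    category = c(rep("sport", length(nouns_sport)),
                 rep("music", length(nouns_music)),
                 rep("contact", length(verbs_contact)),
                 rep("perception", length(verbs_perception))),
    stringsAsFactors = FALSE)
}

## independent brute-force oracle for the run-level generalization statistic
brute_score <- function(pred, obs) {
  n <- length(pred)
  D <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      D[i, j] <- (pred[i] - obs[j])^2
  m <- sum(D) / n^2
  s <- sqrt(sum((D - m)^2) / n^2)
  if (s == 0) return(0)
  Z <- (D - m) / s
  on_diag <- mean(Z[cbind(seq_len(n), seq_len(n))])
  off_diag <- (sum(Z) - sum(diag(Z))) / (n^2 - n)
  on_diag - off_diag
}

## independent Benjamini-Hochberg implementation
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

## small null dataset shared by encoding/group tests
.small_data_cache <- new.env(parent = emptyenv())
small_null_dataset <- function(n_participants = 3, dims = c(10, 10, 10),
                               seed = 5) {
  key <- paste("null", n_participants, paste(dims, collapse = "x"), seed)
  if (!exists(key, envir = .small_data_cache)) {
    ds <- generate_dataset(cached_design(1), null_truth(voxel_grid(dims)),
                           n_participants = n_participants, seed = seed)
    assign(key, ds, envir = .small_data_cache)
  }
  get(key, envir = .small_data_cache)
}

lexicon_nouns_lemmas <- function(lex) lex$lemma[lex$word_class == "noun"]
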