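#' Enumerate the full sentence pool
#'
#' Builds every ordered (agent, verb, patient) combination from a lexicon,
#' excluding sentences whose agent and patient are the same noun. With the
#' built-in 16-noun / 16-verb lexicon this yields 16 x 15 x 16 = 3,840
#' candidate sentences.
#'
#' @param lexicon A lexicon data frame (see [default_lexicon()]).
#' @return A data frame with columns `agent`, `verb`, `patient` (lemmas) and
#'   the lexicon attached as attribute `"lexicon"`.
#' @export
#' @examples
#' pool <- enumerate_pool(default_lexicon())
#' nrow(pool)  # 3840
enumerate_pool <- function(lexicon = default_lexicon()) {
  lexicon <- validate_lexicon(lexicon)
  nouns <- lexicon_nouns(lexicon)$lemma
  verbs <- lexicon_verbs(lexicon)$lemma
  if (length(nouns) < 2L || length(verbs) < 1L)
    abort("need at least 2 nouns and 1 verb", "invalid_lexicon")
  grid <- expand.grid(patient = nouns, verb = verbs, agent = nouns,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$agent != grid$patient, c("agent", "verb", "patient")]
  rownames(grid) <- NULL
  structure(grid, lexicon = lexicon)
}

sentence_categories <- function(sent, lexicon) {
  cat <- category_of(lexicon)
  miss <- setdiff(unique(c(sent$agent, sent$verb, sent$patient)), names(cat))
  if (length(miss))
    abort(paste("lemmas not in lexicon:", paste(miss, collapse = ", ")),
          "unknown_item")
  data.frame(acat = unname(cat[sent$agent]),
             vcat = unname(cat[sent$verb]),
             pcat = unname(cat[sent$patient]),
             stringsAsFactors = FALSE)
}

pattern_id <- function(sent, lexicon) {
  cc <- sentence_categories(sent, lexicon)
  paste(cc$acat, cc$vcat, cc$pcat, sep = "|")
}

#' Select a balanced sentence set from the pool
#'
#' Chooses `n_target` sentences such that (i) every verb occurs
#' `n_target / 16` times, (ii) every noun occurs `n_target / 16` times in the
#' agent role and the same number of times in the patient role, (iii) every
#' (noun, verb) pair occurs at least once with the noun as agent and at least
#' once with the noun as patient, (iv) every sentence-level category pattern
#' (agent category x verb category x patient category, 8 patterns) occurs
#' `n_target / 8` times, and (v) repeated unordered noun pairs are minimized
#' greedily. The default `n_target = 288` gives 18 occurrences per verb and
#' per noun-role and 36 sentences per category pattern.
#'
#' The set is built constructively: per-verb category-cell counts are scheduled
#' cyclically so cell totals are exact, per-verb agent/patient noun multisets
#' contain each compatible noun once plus globally scheduled extras, and
#' agents are paired with patients greedily by lowest current pair usage with
#' local repair to avoid identical agent/patient nouns.
#'
#' @param pool Output of [enumerate_pool()].
#' @param n_target Number of sentences; must be divisible by 16 and by 8, and
#'   at least 256 so that noun-verb-role coverage is feasible.
#' @param seed Integer seed; the same seed reproduces the same set.
#' @return A data frame of sentences (`agent`, `verb`, `patient`, `voice`,
#'   `passive_order`, `trial_type`), voice unset (`NA`), with the lexicon
#'   attached.
#' @export
select_balanced_set <- function(pool, n_target = 288, seed = 1) {
  lexicon <- attr(pool, "lexicon") %||% default_lexicon()
  nouns <- lexicon_nouns(lexicon)
  verbs <- lexicon_verbs(lexicon)
  if (nrow(nouns) != 16L || nrow(verbs) != 16L)
    abort("balanced selection requires the 16-noun / 16-verb lexicon",
          "constraint_infeasible")
  if (n_target %% 16L != 0L || n_target %% 8L != 0L)
    abort("n_target must be divisible by 16 and by 8", "constraint_infeasible")
  k <- n_target %/% 16L            # sentences per verb = noun-role count
  if (k < 16L)
    abort(paste("constraint infeasible: noun-verb-role coverage needs at",
                "least 16 sentences per verb (n_target >= 256)"),
          "constraint_infeasible")
  for (try in seq_len(25L)) {
    res <- with_seed(derive_seed(seed, 101L, try),
                     build_balanced_once(lexicon, k))
    if (!is.null(res)) {
      res$voice <- NA_character_
      res$passive_order <- NA_character_
      res$trial_type <- "production"
      return(structure(res, lexicon = lexicon))
    }
  }
  abort("constraint infeasible: could not pair agents and patients without identical nouns",
        "constraint_infeasible")
}

## One seeded attempt at the constructive balanced design; NULL on failure.
build_balanced_once <- function(lexicon, k) {
  nouns <- lexicon_nouns(lexicon)
  verbs <- lexicon_verbs(lexicon)
  ncat <- split(nouns$lemma, nouns$category)    # $music, $sport
  q <- k - 16L                                   # extra appearances per noun-role
  ## global queues of extra noun appearances, one per role x noun category
  queue <- list()
  for (role in c("agent", "patient"))
    for (cc in c("sport", "music"))
      queue[[paste(role, cc)]] <- sample(rep(ncat[[cc]], q))
  qpos <- stats::setNames(rep(1L, 4L), names(queue))
  pop <- function(key, n) {
    if (n == 0L) return(character(0))
    i <- qpos[[key]]
    out <- queue[[key]][i:(i + n - 1L)]
    qpos[[key]] <<- i + n
    out
  }
  all_nouns <- nouns$lemma
  pair_use <- matrix(0L, 16L, 16L, dimnames = list(all_nouns, all_nouns))
  bump <- function(a, p, d = 1L) {
    pair_use[a, p] <<- pair_use[a, p] + d
    pair_use[p, a] <<- pair_use[p, a] + d
  }
  ## greedy pairing within one category cell, avoiding agent == patient
  pair_cell <- function(agents, patients) {
    agents <- sample(agents)
    patients <- sample(patients)
    ra <- character(0); rp <- character(0)
    for (a in agents) {
      cand <- patients[patients != a]
      if (!length(cand)) {
        ## all remaining patients equal the agent: swap with an earlier pair
        e <- which(rp != a & ra != a)
        if (!length(e)) return(NULL)
        e <- e[1L]
        p_old <- rp[e]
        bump(ra[e], p_old, -1L)
        rp[e] <- patients[1L]
        bump(ra[e], rp[e])
        patients <- patients[-1L]
        ra <- c(ra, a); rp <- c(rp, p_old)
        bump(a, p_old)
      } else {
        use <- pair_use[a, cand]
        p <- cand[which(use == min(use))]
        p <- p[sample.int(length(p), 1L)]
        patients <- patients[-match(p, patients)]
        ra <- c(ra, a); rp <- c(rp, p)
        bump(a, p)
      }
    }
    list(agent = ra, patient = rp)
  }

  cells <- list(c("sport", "sport"), c("sport", "music"),
                c("music", "sport"), c("music", "music"))
  b <- k %/% 4L
  r <- k - 4L * b
  out_a <- character(0); out_v <- character(0); out_p <- character(0)
  for (vc in c("contact", "perception")) {
    vlist <- verbs$lemma[verbs$category == vc]
    cyc <- 0L
    for (v in vlist) {
      cnt <- rep(b, 4L)
      if (r > 0L) {
        extra <- ((cyc + seq_len(r) - 1L) %% 4L) + 1L
        cnt[extra] <- cnt[extra] + 1L
        cyc <- cyc + r
      }
      sA <- cnt[1L] + cnt[2L]; mA <- cnt[3L] + cnt[4L]
      sP <- cnt[1L] + cnt[3L]; mP <- cnt[2L] + cnt[4L]
      ag_s <- sample(c(ncat$sport, pop("agent sport", sA - 8L)))
      ag_m <- sample(c(ncat$music, pop("agent music", mA - 8L)))
      pt_s <- sample(c(ncat$sport, pop("patient sport", sP - 8L)))
      pt_m <- sample(c(ncat$music, pop("patient music", mP - 8L)))
      slot_a <- list(ag_s[seq_len(cnt[1L])],
                     ag_s[cnt[1L] + seq_len(cnt[2L])],
                     ag_m[seq_len(cnt[3L])],
                     ag_m[cnt[3L] + seq_len(cnt[4L])])
      slot_p <- list(pt_s[seq_len(cnt[1L])],
                     pt_m[seq_len(cnt[2L])],
                     pt_s[cnt[1L] + seq_len(cnt[3L])],
                     pt_m[cnt[2L] + seq_len(cnt[4L])])
      for (ci in seq_along(cells)) {
        pr <- pair_cell(slot_a[[ci]], slot_p[[ci]])
        if (is.null(pr)) return(NULL)
        out_a <- c(out_a, pr$agent)
        out_v <- c(out_v, rep(v, length(pr$agent)))
        out_p <- c(out_p, pr$patient)
      }
    }
  }
  ord <- sample.int(length(out_a))
  data.frame(agent = out_a[ord], verb = out_v[ord], patient = out_p[ord],
             stringsAsFactors = FALSE)
}

#' Assign voice and passive word order
#'
#' Within every sentence-level category pattern, half of the sentences are set
#' to active voice and half to passive voice; passive sentences are split as
#' evenly as possible between the two Dutch word orders (verb-final
#' "de bokser wordt door de muzikant herkend" vs. verb-medial "de bokser wordt
#' herkend door de muzikant"), with a global alternation so the two orders are
#' exactly balanced overall whenever the total passive count is even.
#'
#' @param sentences A sentence data frame from [select_balanced_set()].
#' @param seed Integer seed.
#' @return The sentences with `voice` (`"active"`/`"passive"`) and
#'   `passive_order` (`"verb_final"`/`"verb_medial"`/`"not_applicable"`) set.
#' @export
assign_voice_and_order <- function(sentences, seed = 1) {
  if (nrow(sentences) == 0L) return(sentences)
  lexicon <- attr(sentences, "lexicon") %||% default_lexicon()
  pat <- pattern_id(sentences, lexicon)
  voice <- character(nrow(sentences))
  p_order <- rep("not_applicable", nrow(sentences))
  with_seed(derive_seed(seed, 202L), {
    toggle <- 0L
    for (g in split(seq_len(nrow(sentences)), pat)) {
      m <- length(g)
      if (m %% 2L != 0L)
        abort(paste("balancing error: odd sentence count (", m,
                    ") in a category pattern cell"), "balancing_error")
      g <- sample(g)
      act <- g[seq_len(m %/% 2L)]
      pas <- setdiff(g, act)
      voice[act] <- "active"
      voice[pas] <- "passive"
      for (i in pas) {
        p_order[i] <- if (toggle %% 2L == 0L) "verb_final" else "verb_medial"
        toggle <- toggle + 1L
      }
    }
  })
  sentences$voice <- voice
  sentences$passive_order <- p_order
  sentences
}

#' Generate filler sentences
#'
#' Fillers are free-form placeholder sentences drawn from an auxiliary lexicon
#' disjoint from the 16-noun / 16-verb analysis lexicon; their content never
#' enters any analysis.
#'
#' @param n Number of fillers (default 72).
#' @param seed Integer seed.
#' @param aux_nouns,aux_verbs Character vectors to draw from.
#' @return A sentence data frame with `trial_type = "filler"`.
#' @export
make_fillers <- function(n = 72,
                         seed = 1,
                         aux_nouns = c("leraar", "dokter", "buurman", "kapper",
                                       "schilder", "bakker", "tuinman",
                                       "slager", "schrijver", "fotograaf"),
                         aux_verbs = c("helpen", "roepen", "zoeken", "volgen",
                                       "bezoeken", "begroeten", "bedanken",
                                       "storen")) {
  with_seed(derive_seed(seed, 303L), {
    agent <- sample(aux_nouns, n, replace = TRUE)
    patient <- vapply(agent, function(a)
      sample(setdiff(aux_nouns, a), 1L), character(1))
    data.frame(agent = agent,
               verb = sample(aux_verbs, n, replace = TRUE),
               patient = unname(patient),
               voice = sample(c("active", "passive"), n, replace = TRUE),
               passive_order = "not_applicable",
               trial_type = "filler",
               stringsAsFactors = FALSE)
  })
}

#' Schedule sentences into runs
#'
#' Distributes the sentences of interest over `n_runs` runs of 60 trials each
#' (42 production trials of interest, 6 question trials, and 12 fillers per
#' run with the defaults), keeping the distribution of verbs exactly balanced
#' across runs and the per-run counts of every noun-role within `max_diff` of
#' each other.
#'
#' @param sentences Voice-assigned sentences of interest (production +
#'   question trials pooled; 288 with the defaults). If `questions` is `NULL`,
#'   `n_question_per_run * n_runs` of them are marked as question trials.
#' @param fillers Filler sentences from [make_fillers()] (12 per run).
#' @param questions Optional separate data frame of question-trial sentences;
#'   if supplied it is appended to `sentences` with
#'   `trial_type = "question"`.
#' @param n_runs Number of runs (default 6).
#' @param n_production_per_run,n_question_per_run,n_filler_per_run Per-run
#'   composition (defaults 42 / 6 / 12).
#' @param max_diff Maximum allowed across-run difference in per-run counts for
#'   any verb or noun-role (default 2).
#' @param seed Integer seed.
#' @return A `stimulus_design` data frame with columns `run`, `trial_index`,
#'   `trial_type`, `agent`, `verb`, `patient`, `voice`, `passive_order`.
#' @export
schedule_runs <- function(sentences, fillers, questions = NULL, n_runs = 6,
                          n_production_per_run = 42, n_question_per_run = 6,
                          n_filler_per_run = 12, max_diff = 2, seed = 1) {
  lexicon <- attr(sentences, "lexicon") %||% default_lexicon()
  if (!is.null(questions)) {
    questions$trial_type <- "question"
    sentences <- structure(rbind(sentences, questions), lexicon = lexicon)
  }
  n_int <- (n_production_per_run + n_question_per_run) * n_runs
  if (nrow(sentences) != n_int)
    abort(sprintf("schedule error: expected %d sentences of interest, got %d",
                  n_int, nrow(sentences)), "schedule_error")
  if (nrow(fillers) != n_filler_per_run * n_runs)
    abort(sprintf("schedule error: expected %d fillers, got %d",
                  n_filler_per_run * n_runs, nrow(fillers)), "schedule_error")
  for (try in seq_len(40L)) {
    des <- with_seed(derive_seed(seed, 404L, try),
                     schedule_once(sentences, fillers, lexicon, n_runs,
                                   n_question_per_run, max_diff))
    if (!is.null(des)) {
      attr(des, "lexicon") <- lexicon
      attr(des, "n_runs") <- n_runs
      class(des) <- c("stimulus_design", "data.frame")
      return(des)
    }
  }
  abort("schedule error: could not balance runs within max_diff", "schedule_error")
}

schedule_once <- function(sentences, fillers, lexicon, n_runs,
                          n_question_per_run, max_diff) {
  n <- nrow(sentences)
  per_run <- n %/% n_runs
  if (!all(table(sentences$verb) %% n_runs == 0L)) {
    ## verbs cannot be exactly balanced; fall back to plain greedy fill
    run <- sample(rep(seq_len(n_runs), length.out = n))
  } else {
    run <- integer(n)
    for (v in unique(sentences$verb)) {
      idx <- which(sentences$verb == v)
      run[idx] <- sample(rep(seq_len(n_runs), times = length(idx) %/% n_runs))
    }
  }
  if (!"trial_type" %in% names(sentences) ||
      !any(sentences$trial_type == "question")) {
    qi <- sample.int(n, n_question_per_run * n_runs)
    sentences$trial_type <- "production"
    sentences$trial_type[qi] <- "question"
  }
  ## repair 1: per-run question counts, swapping same-verb sentences
  for (it in seq_len(400L)) {
    qc <- tabulate(run[sentences$trial_type == "question"], n_runs)
    if (all(qc == n_question_per_run)) break
    hi <- which.max(qc); lo <- which.min(qc)
    s <- which(run == hi & sentences$trial_type == "question")
    t <- which(run == lo & sentences$trial_type == "production")
    sw <- NULL
    for (i in resample(s)) {
      j <- t[sentences$verb[t] == sentences$verb[i]]
      if (length(j)) { sw <- c(i, j[sample.int(length(j), 1L)]); break }
    }
    if (is.null(sw)) return(NULL)
    run[sw] <- run[rev(sw)]
  }
  if (!all(tabulate(run[sentences$trial_type == "question"], n_runs) ==
           n_question_per_run)) return(NULL)

  ## repair 2: noun-role balance across runs (verb- and type-preserving swaps)
  nouns <- lexicon_nouns(lexicon)$lemma
  counts <- function() {
    rbind(table(factor(sentences$agent, nouns), factor(run, seq_len(n_runs))),
          table(factor(sentences$patient, nouns), factor(run, seq_len(n_runs))))
  }
  cm <- counts()
  obj <- function(m) sum(m^2)
  for (it in seq_len(3000L)) {
    rng <- apply(cm, 1L, function(x) max(x) - min(x))
    if (max(rng) <= max_diff) break
    w <- which.max(rng)
    role <- if (w <= length(nouns)) "agent" else "patient"
    noun <- nouns[((w - 1L) %% length(nouns)) + 1L]
    row <- cm[w, ]
    hi <- which.max(row); lo <- which.min(row)
    s_cand <- which(run == hi & sentences[[role]] == noun)
    improved <- FALSE
    for (i in resample(s_cand)) {
      t_cand <- which(run == lo & sentences$verb == sentences$verb[i] &
                      sentences$trial_type == sentences$trial_type[i] &
                      sentences[[role]] != noun)
      for (j in resample(t_cand)) {
        new_run <- run
        new_run[c(i, j)] <- new_run[c(j, i)]
        run2 <- new_run
        cm2 <- rbind(table(factor(sentences$agent, nouns),
                           factor(run2, seq_len(n_runs))),
                     table(factor(sentences$patient, nouns),
                           factor(run2, seq_len(n_runs))))
        if (obj(cm2) < obj(cm)) {
          run <- new_run; cm <- cm2; improved <- TRUE; break
        }
      }
      if (improved) break
    }
    if (!improved) return(NULL)
  }
  rng <- apply(cm, 1L, function(x) max(x) - min(x))
  if (max(rng) > max_diff) return(NULL)

  sentences$run <- run
  fillers$run <- sample(rep(seq_len(n_runs), length.out = nrow(fillers)))
  cols <- c("run", "trial_type", "agent", "verb", "patient", "voice",
            "passive_order")
  all_tr <- rbind(sentences[, cols], fillers[, cols])
  out <- NULL
  for (r in seq_len(n_runs)) {
    blk <- all_tr[all_tr$run == r, ]
    blk <- blk[sample.int(nrow(blk)), ]
    blk$trial_index <- seq_len(nrow(blk))
    out <- rbind(out, blk)
  }
  rownames(out) <- NULL
  out[, c("run", "trial_index", "trial_type", "agent", "verb", "patient",
          "voice", "passive_order")]
}

#' Build a complete stimulus design
#'
#' Convenience wrapper running [enumerate_pool()], [select_balanced_set()],
#' [assign_voice_and_order()], [make_fillers()] and [schedule_runs()] with the
#' default study constants: 288 balanced sentences of interest (252 production
#' + 36 question trials), 72 fillers, six runs of 60 trials.
#'
#' @param lexicon Lexicon data frame.
#' @param n_target Size of the balanced sentence-of-interest set.
#' @param n_runs Number of runs.
#' @param seed Integer seed.
#' @return A `stimulus_design` data frame (see [schedule_runs()]).
#' @export
#' @examples
#' \donttest{
#' des <- build_design(seed = 1)
#' table(des$run, des$trial_type)
#' }
build_design <- function(lexicon = default_lexicon(), n_target = 288,
                         n_runs = 6, seed = 1) {
  n_quest <- n_target %/% 8L        # question trials: 36 of 288
  if (n_quest %% n_runs != 0L || (n_target - n_quest) %% n_runs != 0L)
    abort("n_target and n_runs incompatible with the 42/6/12 run composition",
          "schedule_error")
  pool <- enumerate_pool(lexicon)
  sel <- select_balanced_set(pool, n_target = n_target, seed = seed)
  sel <- assign_voice_and_order(sel, seed = seed)
  fillers <- make_fillers(n = 2L * n_quest, seed = seed)
  schedule_runs(sel, fillers, n_runs = n_runs,
                n_production_per_run = (n_target - n_quest) %/% n_runs,
                n_question_per_run = n_quest %/% n_runs,
                n_filler_per_run = 2L * n_quest %/% n_runs, seed = seed)
}

#' @export
print.stimulus_design <- function(x, ...) {
  cat("Stimulus design:", nrow(x), "trials in", length(unique(x$run)),
      "runs\n")
  print(table(run = x$run, trial_type = x$trial_type))
  invisible(x)
}

#' Audit a stimulus design against the balance constraints
#'
#' Checks run composition, verb / noun-role / category-pattern balance of the
#' sentences of interest, voice and passive-order halves, and the across-run
#' balance tolerance. Fails with an informative error listing every violated
#' constraint.
#'
#' @param design A `stimulus_design` data frame.
#' @param max_diff Across-run tolerance for verb and noun-role counts.
#' @return Invisibly `TRUE` if all checks pass.
#' @export
audit_design <- function(design, max_diff = 2) {
  lexicon <- attr(design, "lexicon") %||% default_lexicon()
  fail <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) fail <<- c(fail, msg)
  runs <- sort(unique(design$run))
  comp <- table(factor(design$run, runs), design$trial_type)
  chk(all(comp[, "production"] == comp[1, "production"]),
      "unequal production trials per run")
  soi <- design[design$trial_type %in% c("production", "question"), ]
  nouns <- lexicon_nouns(lexicon)$lemma
  verbs <- lexicon_verbs(lexicon)$lemma
  vt <- table(factor(soi$verb, verbs))
  chk(length(unique(vt)) == 1L, "unequal verb totals")
  at <- table(factor(soi$agent, nouns))
  pt <- table(factor(soi$patient, nouns))
  chk(length(unique(at)) == 1L, "unequal agent-role totals")
  chk(length(unique(pt)) == 1L, "unequal patient-role totals")
  pat <- table(pattern_id(soi, lexicon))
  chk(length(pat) == 8L && length(unique(pat)) == 1L,
      "unequal category-pattern totals")
  chk(sum(soi$voice == "active") == nrow(soi) / 2, "voice not split in half")
  chk(sum(soi$passive_order == "verb_final") ==
      sum(soi$passive_order == "verb_medial"),
      "passive word orders not split in half")
  cov_a <- table(factor(soi$agent, nouns), factor(soi$verb, verbs))
  cov_p <- table(factor(soi$patient, nouns), factor(soi$verb, verbs))
  chk(all(cov_a >= 1), "some (noun, verb) pair never occurs with noun as agent")
  chk(all(cov_p >= 1), "some (noun, verb) pair never occurs with noun as patient")
  pr <- table(factor(soi$verb, verbs), factor(soi$run, runs))
  chk(max(apply(pr, 1, function(x) max(x) - min(x))) <= max_diff,
      "per-run verb counts exceed tolerance")
  na <- table(factor(soi$agent, nouns), factor(soi$run, runs))
  np <- table(factor(soi$patient, nouns), factor(soi$run, runs))
  chk(max(apply(rbind(na, np), 1, function(x) max(x) - min(x))) <= max_diff,
      "per-run noun-role counts exceed tolerance")
  if (length(fail))
    abort(paste("design audit failed:", paste(fail, collapse = "; ")),
          "audit_error")
  invisible(TRUE)
}

#' Summarize a design or lexicon
#'
#' For a stimulus design, tabulates verb, noun-role and category-pattern
#' counts over the sentences of interest and reports lexical length
#' statistics; for a bare lexicon, reports the length statistics only. Length
#' statistics are the mean and population standard deviation (denominator n)
#' of lemma character counts within each lexical class.
#'
#' @param x A `stimulus_design` data frame or a lexicon data frame.
#' @return A list of class `design_summary` with elements `length_stats` and,
#'   for designs, `verb_counts`, `agent_counts`, `patient_counts`,
#'   `pattern_counts`.
#' @export
design_summary <- function(x) {
  if (is.null(x) || nrow(x) == 0L)
    abort("empty design or lexicon: nothing to summarize", "empty_summary")
  if ("word_class" %in% names(x)) {
    lexicon <- validate_lexicon(x)
    out <- list(length_stats = length_stats(lexicon))
  } else {
    lexicon <- attr(x, "lexicon") %||% default_lexicon()
    soi <- x[x$trial_type %in% c("production", "question"), , drop = FALSE]
    out <- list(
      verb_counts = table(soi$verb),
      agent_counts = table(soi$agent),
      patient_counts = table(soi$patient),
      pattern_counts = table(pattern_id(soi, lexicon)),
      length_stats = length_stats(lexicon))
  }
  class(out) <- "design_summary"
  out
}

length_stats <- function(lexicon) {
  cls <- split(lexicon$length_chars,
               paste(lexicon$word_class, lexicon$category))
  do.call(rbind, lapply(names(cls), function(nm) {
    data.frame(class = nm, n = length(cls[[nm]]),
               mean_length = mean(cls[[nm]]),
               sd_length = pop_sd(cls[[nm]]),
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.design_summary <- function(x, ...) {
  cat("Lexical length statistics (population SD):\n")
  print(x$length_stats, row.names = FALSE)
  if (!is.null(x$pattern_counts)) {
    cat("\nCategory-pattern counts (agent|verb|patient):\n")
    print(x$pattern_counts)
  }
  invisible(x)
}

#' Write / read a stimulus design as TSV
#'
#' @param design A `stimulus_design` data frame.
#' @param path Output / input file path.
#' @return `read_design` returns the design with the default lexicon attached.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @param lexicon Lexicon to attach on read.
#' @export
read_design <- function(path, lexicon = default_lexicon()) {
  des <- utils::read.delim(path, stringsAsFactors = FALSE)
  attr(des, "lexicon") <- lexicon
  attr(des, "n_runs") <- length(unique(des$run))
  class(des) <- c("stimulus_design", "data.frame")
  des
}
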