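## Encoding models map a sentence to a binary predictor vector. Thematic
## roles are deep roles: the agent slot holds the deep subject (agent of a
## contact verb, experiencer of a perception verb) and the patient slot the
## deep object (patient / stimulus), so featurization never depends on voice
## or surface word order.

MODEL_NAMES <- c("bag_of_nouns_cat", "broad_roles", "narrow_roles",
                 "bag_of_verbs", "bag_of_nouns_specific",
                 "noun_specific_broad_roles", "full_relational")

## noun category display codes: music -> M, sport -> A (athlete)
cat_code <- c(music = "M", sport = "A")

#' Construct an encoding-model specification
#'
#' Seven models describe a sentence at increasing relational specificity:
#' `bag_of_nouns_cat` (2 predictors: noun categories present),
#' `broad_roles` (8: noun category x thematic role, roles tied to the verb
#' category: contact verbs take agent/patient, perception verbs
#' experiencer/stimulus), `narrow_roles` (64: noun category x verb x deep
#' role), `bag_of_verbs` (16: verb identity), `bag_of_nouns_specific`
#' (16: noun identity), `noun_specific_broad_roles` (64: noun identity x
#' broad thematic role) and `full_relational` (512: noun x verb x deep role).
#'
#' @param name One of the seven model names (see [model_names()]).
#' @param lexicon Lexicon defining the noun and verb inventory.
#' @return An object of class `encoding_model` with elements `name`,
#'   `predictor_labels` and the lexicon.
#' @export
#' @examples
#' m <- encoding_model("broad_roles")
#' m$predictor_labels
encoding_model <- function(name, lexicon = default_lexicon()) {
  name <- match.arg(name, MODEL_NAMES)
  nouns <- lexicon_nouns(lexicon)$lemma
  verbs <- lexicon_verbs(lexicon)$lemma
  codes <- unname(cat_code[c("music", "sport")])
  broad <- c("agent", "patient", "experiencer", "stimulus")
  labels <- switch(name,
    bag_of_nouns_cat = codes,
    broad_roles = c(paste0("M-as-", broad[1:2]), paste0("A-as-", broad[1:2]),
                    paste0("M-as-", broad[3:4]), paste0("A-as-", broad[3:4])),
    narrow_roles = as.vector(vapply(verbs, function(v)
      paste0(rep(codes, each = 2), "-", v, "-", c("subj", "obj")),
      character(4))),
    bag_of_verbs = verbs,
    bag_of_nouns_specific = nouns,
    noun_specific_broad_roles = as.vector(vapply(nouns, function(n)
      paste0(n, "-as-", broad), character(4))),
    full_relational = as.vector(vapply(verbs, function(v)
      paste0(rep(nouns, each = 2), "-", v, "-", c("subj", "obj")),
      character(32))))
  stopifnot(!anyDuplicated(labels))
  structure(list(name = name, predictor_labels = labels, lexicon = lexicon),
            class = "encoding_model")
}

#' @export
print.encoding_model <- function(x, ...) {
  cat("Encoding model:", x$name, "-", length(x$predictor_labels),
      "binary predictors\n")
  invisible(x)
}

#' @rdname encoding_model
#' @export
model_names <- function() MODEL_NAMES

#' Number of predictors of an encoding model
#'
#' @param model An `encoding_model` or a model name.
#' @param lexicon Lexicon (used when `model` is a name).
#' @return Integer predictor count (2, 8, 64, 16, 16, 64 or 512).
#' @export
predictor_count <- function(model, lexicon = default_lexicon()) {
  if (is.character(model)) model <- encoding_model(model, lexicon)
  length(model$predictor_labels)
}

## deep roles of the two noun slots given the verb category
deep_roles <- function(vcat) {
  if (vcat == "contact") c("agent", "patient") else c("experiencer", "stimulus")
}

#' Featurize one sentence under an encoding model
#'
#' Maps a sentence to its binary predictor vector. Role assignment depends
#' only on the deep (thematic) structure — agent/patient nouns and the verb —
#' never on voice or surface order, so an active sentence and its passivized
#' form have identical features.
#'
#' @param sentence A list or one-row data frame with `agent`, `verb`,
#'   `patient` lemmas.
#' @param model An `encoding_model` object or model name.
#' @return A named binary vector over the model's predictor labels.
#' @export
#' @examples
#' s <- list(agent = "surfer", verb = "schoppen", patient = "muzikant")
#' featurize(s, "bag_of_nouns_cat")  # M = 1, A = 1
featurize <- function(sentence, model) {
  if (is.character(model)) model <- encoding_model(model)
  lexicon <- model$lexicon
  cat <- category_of(lexicon)
  a <- sentence$agent; v <- sentence$verb; p <- sentence$patient
  miss <- setdiff(c(a, v, p), names(cat))
  if (length(miss))
    abort(paste("unknown lexical item(s):", paste(miss, collapse = ", ")),
          "unknown_item")
  ac <- cat_code[[cat[[a]]]]; pc <- cat_code[[cat[[p]]]]
  roles <- deep_roles(cat[[v]])
  x <- stats::setNames(rep(0, length(model$predictor_labels)),
                       model$predictor_labels)
  on <- switch(model$name,
    bag_of_nouns_cat = unique(c(ac, pc)),
    broad_roles = c(paste0(ac, "-as-", roles[1]), paste0(pc, "-as-", roles[2])),
    narrow_roles = c(paste0(ac, "-", v, "-subj"), paste0(pc, "-", v, "-obj")),
    bag_of_verbs = v,
    bag_of_nouns_specific = unique(c(a, p)),
    noun_specific_broad_roles = c(paste0(a, "-as-", roles[1]),
                                  paste0(p, "-as-", roles[2])),
    full_relational = c(paste0(a, "-", v, "-subj"), paste0(p, "-", v, "-obj")))
  x[on] <- 1
  x
}

#' Build a design matrix for a set of sentences
#'
#' @param sentences Data frame of sentences (`agent`, `verb`, `patient`).
#' @param model An `encoding_model` or model name.
#' @param ids Sentence identifiers (default: row sequence); must be unique.
#' @return A binary matrix, sentences x predictors, with `ids` as row names
#'   and the model attached as attribute `"model"`.
#' @export
build_design_matrix <- function(sentences, model, ids = NULL) {
  if (is.character(model)) model <- encoding_model(model)
  if (nrow(sentences) == 0L)
    abort("no sentences to featurize", "empty_input")
  ids <- ids %||% seq_len(nrow(sentences))
  if (anyDuplicated(ids))
    abort("duplicate sentence ids", "id_collision")
  X <- t(vapply(seq_len(nrow(sentences)), function(i)
    featurize(sentences[i, ], model),
    numeric(length(model$predictor_labels))))
  rownames(X) <- as.character(ids)
  colnames(X) <- model$predictor_labels
  structure(X, model = model$name)
}

#' Look up lemmas by English gloss
#'
#' Convenience helper for constructing example sentences with the built-in
#' lexicon's English glosses (e.g. `"surfer"`, `"kick"`, `"musician"`).
#'
#' @param agent,verb,patient English glosses present in the lexicon.
#' @param lexicon Lexicon data frame.
#' @return A list with `agent`, `verb`, `patient` lemmas.
#' @export
sentence_from_gloss <- function(agent, verb, patient,
                                lexicon = default_lexicon()) {
  lk <- stats::setNames(lexicon$lemma, lexicon$gloss)
  miss <- setdiff(c(agent, verb, patient), names(lk))
  if (length(miss))
    abort(paste("unknown gloss(es):", paste(miss, collapse = ", ")),
          "unknown_item")
  list(agent = lk[[agent]], verb = lk[[verb]], patient = lk[[patient]])
}
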