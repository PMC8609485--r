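#' Default placeholder lexicons
#'
#' Twenty noun and fifteen verb pairs (L2 English form, L1 German form) from
#' a beginner's curriculum, shipped as TSV under `inst/extdata/`. The
#' orthographic letter difference between forms is computed with a
#' case-insensitive Levenshtein distance; nouns differing in fewer than two
#' letters (e.g. *house*/*Haus*) are ineligible as switch targets.
#'
#' @return list of data.frames `nouns` and `verbs`, each with `l2`, `l1`
#'   and (nouns only) `letter_diff`, `switch_eligible`.
#' @export
default_lexicon <- function() {
  nouns <- utils::read.delim(
    system.file("extdata", "lexicon_nouns.tsv", package = "l2eeg"),
    stringsAsFactors = FALSE)
  verbs <- utils::read.delim(
    system.file("extdata", "lexicon_verbs.tsv", package = "l2eeg"),
    stringsAsFactors = FALSE)
  list(nouns = annotate_letter_diff(nouns), verbs = verbs)
}

#' Annotate a noun lexicon with the L1/L2 letter difference
#' @param nouns data.frame with `l2`, `l1`.
#' @return the data.frame with `letter_diff` and `switch_eligible` added.
#' @export
annotate_letter_diff <- function(nouns) {
  nouns$letter_diff <- as.integer(mapply(function(a, b) {
    utils::adist(tolower(a), tolower(b))
  }, nouns$l2, nouns$l1))
  nouns$switch_eligible <- nouns$letter_diff >= 2L
  nouns
}

#' Generate the 2x2 sentence stimulus table
#'
#' Builds `n_sentences` compound sentences of 9-12 words, each ending in a
#' target noun, and emits every sentence in all four conditions (switch /
#' no-switch crossed with congruent / incongruent), i.e. `4 * n_sentences`
#' stimulus rows. Nouns fill subject and object slots and verbs fill the
#' verb slot in balanced round-robin order, so item reuse is as even as the
#' lexicon allows; sentence-final targets are drawn only from nouns whose
#' L1/L2 forms differ in at least two letters, so a language switch is
#' always orthographically detectable. Incongruent versions replace the
#' target with a different (semantically implausible) eligible noun.
#'
#' Note on quotas: literal per-item usage counts (each noun four times, each
#' verb twice) cannot fill the slot budget of 80 two-noun sentences; the
#' round-robin scheme keeps usage within one of the minimum attainable
#' imbalance instead.
#'
#' @param n_sentences number of base sentences (80 in the emulated design).
#' @param nouns,verbs lexicon data.frames (see [default_lexicon()]); nouns
#'   need `l2`, `l1` and are annotated with eligibility if missing.
#' @param seed integer seed (controls template jitter only; slot filling is
#'   deterministic round-robin).
#' @return data.frame with one row per sentence x condition: `sentence_id`,
#'   `condition`, `switch`, `congruent`, `subject_noun`, `verb`,
#'   `target_l2`, `target_presented`, `n_words`, `text`.
#' @export
generate_stimulus_list <- function(n_sentences, nouns = NULL, verbs = NULL,
                                   seed = 1L) {
  if (is.null(nouns) || is.null(verbs)) {
    lex <- default_lexicon()
    if (is.null(nouns)) nouns <- lex$nouns
    if (is.null(verbs)) verbs <- lex$verbs
  }
  if (is.null(nouns$switch_eligible)) nouns <- annotate_letter_diff(nouns)
  if (nrow(verbs) < 1L) stop("lexicon too small: no verbs", call. = FALSE)
  if (nrow(nouns) < 2L) stop("lexicon too small: need >= 2 nouns", call. = FALSE)
  elig <- which(nouns$switch_eligible)
  if (length(elig) < 2L) {
    stop("lexicon too small: need >= 2 switch-eligible nouns (have ",
         length(elig), ")", call. = FALSE)
  }

  templates <- c(
    "The %s that does not %s much %ss a %s",            # 10 words
    "The %s that likes to %s often %ss a %s",           # 10
    "The %s that can %s very well %ss a big %s",        # 12
    "The %s that wants to %s %ss a %s",                 # 9
    "The %s that does not want to %s %ss a %s"          # 11
  )
  withr_seed(seed, {
    tmpl_idx <- sample(rep_len(seq_along(templates), n_sentences))
  })

  rows <- vector("list", 4L * n_sentences)
  k <- 0L
  for (i in seq_len(n_sentences)) {
    subj <- nouns$l2[(i - 1L) %% nrow(nouns) + 1L]
    verb <- verbs$l2[(i - 1L) %% nrow(verbs) + 1L]
    obj_i <- elig[(i - 1L) %% length(elig) + 1L]
    if (nouns$l2[obj_i] == subj) {
      obj_i <- elig[i %% length(elig) + 1L]
    }
    inc_i <- elig[(i - 1L + length(elig) %/% 2L) %% length(elig) + 1L]
    if (inc_i == obj_i) inc_i <- elig[i %% length(elig) + 1L]
    for (sw in c(FALSE, TRUE)) {
      for (cg in c(TRUE, FALSE)) {
        tgt_i <- if (cg) obj_i else inc_i
        presented <- if (sw) nouns$l1[tgt_i] else nouns$l2[tgt_i]
        text <- sprintf(templates[tmpl_idx[i]], subj, verb, verb, presented)
        k <- k + 1L
        rows[[k]] <- data.frame(
          sentence_id = i,
          condition = paste0(if (sw) "switch" else "no_switch",
                             if (cg) "_congruent" else "_incongruent"),
          switch = sw, congruent = cg,
          subject_noun = subj, verb = verb,
          target_l2 = nouns$l2[tgt_i], target_presented = presented,
          n_words = length(strsplit(text, " ")[[1L]]),
          text = text, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
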