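# Porter stemmer (the 1980 algorithm), implemented directly because no
# stemming package ships with the package's dependency set and the stem
# operation is a first-class primitive of the preprocessing pipeline.
#
# Conventions below follow the original description:
#   m      -- the "measure" of a stem, the number of VC blocks in [C](VC)^m[V]
#   *v*    -- stem contains a vowel
#   *d     -- stem ends in a double consonant
#   *o     -- stem ends cvc where the final c is not w, x or y

# Map a lowercase word to its consonant/vowel pattern ("C"/"V" string).
# y is a vowel exactly when preceded by a consonant.
porter_cv <- function(word) {
  p <- gsub("[aeiou]", "V", word)
  p <- gsub("[^Vy]", "C", p)
  while (grepl("y", p, fixed = TRUE)) {
    p <- sub("^y", "C", p)
    p2 <- gsub("Vy", "VC", p)
    p2 <- gsub("Cy", "CV", p2)
    if (identical(p2, p)) break
    p <- p2
  }
  p
}

porter_measure <- function(stem) {
  if (!nzchar(stem)) return(0L)
  q <- gsub("C+", "C", gsub("V+", "V", porter_cv(stem)))
  m <- gregexpr("VC", q, fixed = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

porter_has_vowel <- function(stem) grepl("V", porter_cv(stem), fixed = TRUE)

porter_double_cons <- function(stem) {
  n <- nchar(stem)
  n >= 2 &&
    substr(stem, n, n) == substr(stem, n - 1, n - 1) &&
    grepl("CC$", porter_cv(stem))
}

porter_cvc <- function(stem) {
  n <- nchar(stem)
  if (n < 3) return(FALSE)
  grepl("CVC$", porter_cv(stem)) &&
    !substr(stem, n, n) %in% c("w", "x", "y")
}

ends_with <- function(w, suf) {
  nchar(w) >= nchar(suf) &&
    substr(w, nchar(w) - nchar(suf) + 1, nchar(w)) == suf
}

chop <- function(w, k) substr(w, 1, nchar(w) - k)

# Rule tables for steps 2-4: suffix, replacement, minimum measure (exclusive).
porter_step2_rules <- list(
  c("ational", "ate"), c("tional", "tion"), c("enci", "ence"), c("anci", "ance"),
  c("izer", "ize"), c("abli", "able"), c("alli", "al"), c("entli", "ent"),
  c("eli", "e"), c("ousli", "ous"), c("ization", "ize"), c("ation", "ate"),
  c("ator", "ate"), c("alism", "al"), c("iveness", "ive"), c("fulness", "ful"),
  c("ousness", "ous"), c("aliti", "al"), c("iviti", "ive"), c("biliti", "ble")
)

porter_step3_rules <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", "")
)

porter_step4_sufs <- c(
  "al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
  "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive", "ize"
)

porter_stem_one <- function(w) {
  if (nchar(w) <= 2) return(w)

  # Step 1a
  if (ends_with(w, "sses")) w <- chop(w, 2)
  else if (ends_with(w, "ies")) w <- chop(w, 2)
  else if (!ends_with(w, "ss") && ends_with(w, "s")) w <- chop(w, 1)

  # Step 1b
  if (ends_with(w, "eed")) {
    if (porter_measure(chop(w, 3)) > 0) w <- chop(w, 1)
  } else {
    fired <- FALSE
    if (ends_with(w, "ed") && porter_has_vowel(chop(w, 2))) {
      w <- chop(w, 2); fired <- TRUE
    } else if (ends_with(w, "ing") && porter_has_vowel(chop(w, 3))) {
      w <- chop(w, 3); fired <- TRUE
    }
    if (fired) {
      if (ends_with(w, "at") || ends_with(w, "bl") || ends_with(w, "iz")) {
        w <- paste0(w, "e")
      } else if (porter_double_cons(w) &&
                 !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
        w <- chop(w, 1)
      } else if (porter_measure(w) == 1 && porter_cvc(w)) {
        w <- paste0(w, "e")
      }
    }
  }

  # Step 1c
  if (ends_with(w, "y") && porter_has_vowel(chop(w, 1))) {
    w <- paste0(chop(w, 1), "i")
  }

  # Step 2 (longest matching suffix; condition m(stem) > 0)
  hit <- NULL
  for (r in porter_step2_rules) {
    if (ends_with(w, r[1]) && (is.null(hit) || nchar(r[1]) > nchar(hit[1]))) hit <- r
  }
  if (!is.null(hit)) {
    stem <- chop(w, nchar(hit[1]))
    if (porter_measure(stem) > 0) w <- paste0(stem, hit[2])
  }

  # Step 3 (condition m(stem) > 0)
  hit <- NULL
  for (r in porter_step3_rules) {
    if (ends_with(w, r[1]) && (is.null(hit) || nchar(r[1]) > nchar(hit[1]))) hit <- r
  }
  if (!is.null(hit)) {
    stem <- chop(w, nchar(hit[1]))
    if (porter_measure(stem) > 0) w <- paste0(stem, hit[2])
  }

  # Step 4 (condition m(stem) > 1; "ion" additionally needs stem ending s/t)
  hit <- ""
  for (suf in porter_step4_sufs) {
    if (ends_with(w, suf) && nchar(suf) > nchar(hit)) hit <- suf
  }
  if (nzchar(hit)) {
    stem <- chop(w, nchar(hit))
    ok <- porter_measure(stem) > 1
    if (ok && hit == "ion") {
      ok <- nzchar(stem) && substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")
    }
    if (ok) w <- stem
  }

  # Step 5a
  if (ends_with(w, "e")) {
    stem <- chop(w, 1)
    m <- porter_measure(stem)
    if (m > 1 || (m == 1 && !porter_cvc(stem))) w <- stem
  }
  # Step 5b
  if (porter_measure(w) > 1 && porter_double_cons(w) && ends_with(w, "l")) {
    w <- chop(w, 1)
  }
  w
}

# memoized stem cache; vocabulary reuse across corpora makes this worthwhile
.porter_cache <- new.env(parent = emptyenv())

#' Stem tokens with the Porter algorithm
#'
#' Reduces lowercase tokens to their Porter stems, the suffix-stripping
#' normalization used when building term-document matrices (e.g.
#' "advanced" and "advancing" both map to the stem "advanc"). The
#' transformation is idempotent: stemming a stem returns it unchanged.
#'
#' @param tokens Character vector of lowercase tokens.
#' @return Character vector of stems, same length and order as `tokens`.
#' @examples
#' stem_tokens(c("interactions", "advanced", "drug"))
#' @export
stem_tokens <- function(tokens) {
  if (length(tokens) == 0) return(character())
  if (!is.character(tokens)) stop_altriage("tokens must be a character vector", "type")
  uniq <- unique(tokens)
  known <- vapply(uniq, function(u) exists(u, envir = .porter_cache, inherits = FALSE),
                  logical(1))
  for (u in uniq[!known]) {
    assign(u, porter_stem_one(u), envir = .porter_cache)
  }
  out <- vapply(tokens, function(t) get(t, envir = .porter_cache, inherits = FALSE),
                character(1), USE.NAMES = FALSE)
  out
}
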