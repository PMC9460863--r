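#' Valence-arousal quadrant vocabulary
#'
#' The four quadrants of the valence-arousal plane, arousal-first spelling:
#' HAPV (high arousal, positive valence), HANV (high arousal, negative
#' valence), LANV (low arousal, negative valence), LAPV (low arousal,
#' positive valence). The valence-first synonyms sometimes seen for the two
#' "opposite trend" quadrants map as HVLA = LAPV and LVHA = HANV.
#'
#' @return Character vector of the four quadrant codes, in quadrant order
#'   I-IV (HAPV, HANV, LANV, LAPV).
#' @export
quadrant_levels <- function() c("HAPV", "HANV", "LANV", "LAPV")

#' Emotion label for one quadrant
#'
#' @param quadrant One of [quadrant_levels()], or a valence-first synonym
#'   ("HVLA" for LAPV, "LVHA" for HANV).
#' @return An `emotion_label` with fields `quadrant`, `arousal`
#'   ("high"/"low") and `valence` ("positive"/"negative").
#' @export
#' @examples
#' emotion_label("HAPV")$arousal
emotion_label <- function(quadrant) {
  synonyms <- c(HVLA = "LAPV", LVHA = "HANV")
  if (quadrant %in% names(synonyms)) quadrant <- synonyms[[quadrant]]
  quadrant <- match.arg(quadrant, quadrant_levels())
  structure(
    list(
      quadrant = quadrant,
      arousal = if (substr(quadrant, 1, 1) == "H") "high" else "low",
      valence = if (substr(quadrant, 3, 3) == "P") "positive" else "negative"
    ),
    class = "emotion_label"
  )
}

#' @export
print.emotion_label <- function(x, ...) {
  cat(sprintf("<emotion_label> %s (%s arousal, %s valence)\n",
              x$quadrant, x$arousal, x$valence))
  invisible(x)
}

#' Quadrant code from arousal/valence pair
#' @param arousal "high" or "low".
#' @param valence "positive" or "negative".
#' @return The quadrant code.
#' @export
quadrant_from_axes <- function(arousal = c("high", "low"),
                               valence = c("positive", "negative")) {
  arousal <- match.arg(arousal)
  valence <- match.arg(valence)
  paste0(if (arousal == "high") "HA" else "LA",
         if (valence == "positive") "PV" else "NV")
}

# Deterministic per-module seed derivation from the single run seed, so the
# streams of independent modules do not collide. Knuth multiplicative hash on
# the module-name bytes, folded into [0, 2^31 - 2].
derive_seed <- function(seed, module) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (b in utf8ToInt(module)) h <- (h * 131 + b) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 + h) %% 2147483647)
}

# Run `expr` under a locally-set RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
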