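#' Recognised breed tokens, in canonical precedence order
#'
#' Holstein/Friesian (HF), New Zealand Friesian (NZF), British/unknown
#' Friesian (BF), Jersey (JE), Scandinavian Red (SR), Shorthorn (SH),
#' Ayrshire (AYR), Montbeliarde (MO), Brown Swiss (BS), Meuse Rhine Issel
#' (MRI) and XX for unknown composition. Compound labels are written with
#' components in this order (so a Holstein x Jersey cross is HFJE, never
#' JEHF).
#'
#' @return character vector of breed tokens.
#' @export
breed_vocabulary <- function() {
  c("HF", "NZF", "BF", "JE", "SR", "SH", "AYR", "MO", "BS", "MRI", "XX")
}

# Parse one parent pedigree label into fractional breed contributions.
# Accepts pure tokens ("JE"), x-separated compounds ("JExSH") and majority
# labels ("JEX" = mostly Jersey with unknown remainder). Returns a named
# numeric vector of weights summing to 1.
parse_parent_label <- function(label) {
  vocab <- breed_vocabulary()
  lab <- toupper(trimws(label))
  if (is.na(lab) || !nzchar(lab))
    stop("empty or missing parent breed label", call. = FALSE)
  tokens <- strsplit(lab, "x", fixed = TRUE)[[1]]
  # uppercase input: split on X only where it separates two vocabulary tokens
  if (length(tokens) == 1L && !lab %in% vocab && grepl("X", lab, fixed = TRUE)) {
    parts <- strsplit(lab, "X", fixed = TRUE)[[1]]
    if (length(parts) > 1L && all(parts %in% vocab)) tokens <- parts
  }
  w <- numeric(0)
  share <- 1 / length(tokens)
  for (tok in tokens) {
    tok <- trimws(tok)
    if (tok %in% vocab) {
      w[tok] <- (if (tok %in% names(w)) w[[tok]] else 0) + share
    } else if (nchar(tok) > 1L && endsWith(tok, "X") &&
               substr(tok, 1L, nchar(tok) - 1L) %in% vocab) {
      # majority label: dominant breed gets 3/4 of this parent's share,
      # the unknown remainder 1/4
      core <- substr(tok, 1L, nchar(tok) - 1L)
      w[core] <- (if (core %in% names(w)) w[[core]] else 0) + 0.75 * share
      w["XX"] <- (if ("XX" %in% names(w)) w[["XX"]] else 0) + 0.25 * share
    } else {
      stop("unrecognized breed token '", tok, "' in label '", label, "'",
           call. = FALSE)
    }
  }
  w
}

#' Canonical breed code from sire and dam pedigree labels
#'
#' Produces a parent-sex-symmetric breed code: a purebred Jersey sire and dam
#' give `JE`; a Jersey/Holstein cross is `HFJE` whichever parent is which;
#' parents that share a single majority breed give that breed plus a trailing
#' `X` (for example a Jersey x Shorthorn sire and Jersey x Ayrshire dam give
#' `JEX`). Components of compound labels are ordered by the fixed precedence
#' in [breed_vocabulary()]. Crosses with no single dominant breed collapse to
#' `XX`.
#'
#' @param sire,dam raw pedigree labels (e.g. `"JE"`, `"JExSH"`, `"JEX"`).
#' @return object of class `breed_code`: a list with `canonical_label`,
#'   `component_breeds` (precedence-ordered) and `is_backcross_or_majority`
#'   (`TRUE` iff the label carries a trailing X).
#' @examples
#' canonical_breed_code("JE", "HF")$canonical_label      # "HFJE"
#' canonical_breed_code("JExSH", "JExAYR")$canonical_label  # "JEX"
#' @export
canonical_breed_code <- function(sire, dam) {
  ws <- parse_parent_label(sire)
  wd <- parse_parent_label(dam)
  w <- numeric(0)
  for (b in union(names(ws), names(wd))) {
    w[b] <- 0.5 * (if (b %in% names(ws)) ws[[b]] else 0) +
            0.5 * (if (b %in% names(wd)) wd[[b]] else 0)
  }
  vocab <- breed_vocabulary()
  breeds <- names(w)[w > 1e-9]
  breeds <- breeds[order(match(breeds, vocab))]
  w <- w[breeds]
  eps <- 1e-9

  out <- function(label, comps, flag) {
    structure(list(canonical_label = label,
                   component_breeds = comps,
                   is_backcross_or_majority = flag),
              class = "breed_code")
  }
  if (length(breeds) == 1L)                       # purebred (or pure unknown)
    return(out(breeds, breeds, FALSE))
  if (length(breeds) == 2L && all(abs(w - 0.5) < eps) && !"XX" %in% breeds)
    return(out(paste0(breeds, collapse = ""), breeds, FALSE))
  known <- breeds[breeds != "XX"]
  top <- breeds[w > max(w) - eps]
  if (length(top) == 1L && top != "XX")           # single majority breed
    return(out(paste0(top, "X"), known, TRUE))
  out("XX", known, FALSE)                         # no dominant contribution
}

#' @export
print.breed_code <- function(x, ...) {
  cat("<breed_code> ", x$canonical_label,
      " [", paste(x$component_breeds, collapse = ", "), "]",
      if (x$is_backcross_or_majority) " (majority/backcross)", "\n", sep = "")
  invisible(x)
}

#' Canonical breed labels for vectors of sire/dam labels
#'
#' Vectorised convenience wrapper around [canonical_breed_code()].
#'
#' @param sire,dam character vectors of equal length.
#' @return character vector of canonical labels.
#' @export
canonical_breed_labels <- function(sire, dam) {
  stopifnot(length(sire) == length(dam))
  mapply(function(s, d) canonical_breed_code(s, d)$canonical_label, sire, dam,
         USE.NAMES = FALSE)
}
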