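# Stereochemistry of myo-inositol phosphates.
#
# A phosphorylation pattern on the six-carbon myo-inositol ring is a subset
# of ring locants {1..6}. The ring has one internal mirror symmetry relevant
# to phosphate patterns: reflection through the plane containing C2 and C5,
# which exchanges locants 1<->3 and 4<->6 and fixes 2 and 5. Two patterns
# related by this reflection are enantiomers; a pattern equal to its own
# reflection is meso (achiral). D and L numbering run around the ring in
# opposite directions and are related by the same permutation, hence the
# classic identity 1D-6 = 1L-4.

# the C2/C5 mirror permutation on locants: 1<->3, 4<->6, 2 and 5 fixed
.MIRROR_PERM <- c(3L, 2L, 1L, 6L, 5L, 4L)

# the 2-position carries the ring's single axial substituent (annotation
# constant; no geometry is modelled)
AXIAL_LOCANT <- 2L

#' Create a myo-inositol phosphorylation state
#'
#' A `phospho_state` records which ring positions (locants 1..6) of
#' myo-inositol carry a phosphate, together with the numbering convention
#' (D or L) in which those locants are expressed.
#'
#' @param positions integer vector of distinct ring locants in 1..6
#'   (may be empty: free inositol).
#' @param numbering `"D"` or `"L"`.
#' @return An object of class `phospho_state`: a list with elements
#'   `positions` (sorted integer vector) and `numbering`.
#' @examples
#' phospho_state(c(1, 2, 3, 4, 5))            # D-Ins(1,2,3,4,5)P5
#' phospho_state(4, numbering = "L")          # 1L-4, i.e. the D-6 position
#' @export
phospho_state <- function(positions = integer(), numbering = c("D", "L")) {
  numbering <- match.arg(numbering)
  if (length(positions) == 0) {
    positions <- integer()
  } else {
    if (anyNA(positions)) stop("locants must not contain NA", call. = FALSE)
    pos <- as.integer(positions)
    if (any(pos != positions)) stop("locants must be whole numbers", call. = FALSE)
    if (any(pos < 1L | pos > 6L)) {
      stop("locant outside 1..6: ", paste(pos[pos < 1L | pos > 6L], collapse = ", "),
           call. = FALSE)
    }
    if (anyDuplicated(pos)) stop("duplicate locants", call. = FALSE)
    positions <- sort(pos)
  }
  structure(list(positions = positions, numbering = numbering),
            class = "phospho_state")
}

.assert_state <- function(state) {
  if (!inherits(state, "phospho_state")) {
    # tolerate a bare locant vector for convenience
    return(phospho_state(state))
  }
  state
}

#' @export
print.phospho_state <- function(x, ...) {
  cat(format_name(x), "\n")
  invisible(x)
}

#' @export
format.phospho_state <- function(x, ...) format_name(x)

#' @export
`==.phospho_state` <- function(e1, e2) {
  identical(e1$positions, e2$positions) && identical(e1$numbering, e2$numbering)
}

#' Enantiomeric (mirror-image) phosphorylation pattern
#'
#' Applies the ring's mirror symmetry (the reflection through C2 and C5,
#' exchanging locants 1 and 3 and locants 4 and 6) to a phosphorylation
#' pattern, returning the enantiomer expressed in the same numbering.
#' `mirror()` is an involution: `mirror(mirror(s))` equals `s`.
#'
#' @param state a [phospho_state] (or bare locant vector, taken as D).
#' @return a `phospho_state` in the same numbering.
#' @examples
#' mirror(phospho_state(c(1, 2, 3, 4)))   # Ins(1,2,3,6)P4
#' mirror(phospho_state(c(1, 3, 4, 6)))   # itself: a meso pattern
#' @export
mirror <- function(state) {
  state <- .assert_state(state)
  phospho_state(.MIRROR_PERM[state$positions], numbering = state$numbering)
}

#' Convert a state between D and L numbering
#'
#' D and L locant numbering of myo-inositol run in opposite directions around
#' the ring; the same physical molecule carries locant sets related by the
#' mirror permutation (1<->3, 4<->6). Hence 1D-6 = 1L-4. Converting to the
#' numbering a state is already in is the identity.
#'
#' @param state a [phospho_state].
#' @param target `"D"` or `"L"`.
#' @return the same molecule expressed in `target` numbering.
#' @examples
#' convert_numbering(phospho_state(4, numbering = "L"), "D")  # position 6
#' @export
convert_numbering <- function(state, target = c("D", "L")) {
  state <- .assert_state(state)
  target <- match.arg(target)
  if (target == state$numbering) return(state)
  phospho_state(.MIRROR_PERM[state$positions], numbering = target)
}

#' Enumerate all phosphorylation states with a given phosphate count
#'
#' All distinct locant subsets of size `n_phosphates`, i.e. choose(6, n)
#' stereoisomers of InsPn on the myo-inositol ring, in lexicographic order
#' of the sorted locant tuples. (15 InsP4, 20 InsP3, 15 InsP2 isomers.)
#'
#' @param n_phosphates integer in 0..6.
#' @return list of [phospho_state] (D numbering), lexicographic order.
#' @examples
#' length(enumerate_isomers(4))  # 15
#' @export
enumerate_isomers <- function(n_phosphates) {
  if (length(n_phosphates) != 1 || is.na(n_phosphates) ||
      n_phosphates != as.integer(n_phosphates) ||
      n_phosphates < 0 || n_phosphates > 6) {
    stop("n_phosphates must be a single integer in 0..6", call. = FALSE)
  }
  n <- as.integer(n_phosphates)
  if (n == 0L) return(list(phospho_state()))
  sets <- utils::combn(6L, n, simplify = FALSE)  # combn emits lexicographic order
  lapply(sets, phospho_state)
}

#' Is a phosphorylation pattern meso (achiral)?
#'
#' TRUE iff the pattern equals its own mirror image, in which case there is
#' no D/L distinction for the compound.
#'
#' @param state a [phospho_state].
#' @return logical.
#' @examples
#' is_meso(phospho_state(c(1, 3, 4, 6)))    # TRUE
#' is_meso(phospho_state(c(1, 2, 3, 4, 5))) # FALSE: chiral, written D/L-
#' @export
is_meso <- function(state) {
  state <- .assert_state(state)
  identical(state$positions, sort(.MIRROR_PERM[state$positions]))
}

# lexicographic comparison of equal-length sorted integer vectors:
# negative if a < b, 0 if equal, positive if a > b
.lex_cmp <- function(a, b) {
  d <- a - b
  nz <- which(d != 0L)
  if (length(nz) == 0L) 0L else d[nz[1L]]
}

#' Canonical co-elution class of a phosphorylation state
#'
#' On an achiral anion-exchange HPLC column an enantiomer pair co-elutes as a
#' single peak; a meso compound is a class of its own. The canonical class of
#' a state is named after its representative: the lexicographically smaller
#' of the state and its mirror image, expressed in D numbering. Chiral pairs
#' are displayed with the "D/L-" prefix.
#'
#' @param state a [phospho_state].
#' @return an object of class `isomer_class`: list with `representative`
#'   and `partner` ([phospho_state] or `NULL`), `chirality`
#'   (`"meso"` or `"chiral_pair"`), `display_name`, `n_phosphates`.
#' @examples
#' canonical_class(phospho_state(c(2, 3, 4, 5, 6)))$display_name # D/L-Ins(1,2,4,5,6)P5
#' canonical_class(phospho_state(c(1, 3, 4, 6)))$chirality       # meso
#' @export
canonical_class <- function(state) {
  state <- convert_numbering(.assert_state(state), "D")
  m <- mirror(state)
  cmp <- .lex_cmp(state$positions, m$positions)
  if (cmp == 0L) {
    rep_state <- state
    partner <- NULL
    chirality <- "meso"
  } else {
    rep_state <- if (cmp < 0L) state else m
    partner <- mirror(rep_state)
    chirality <- "chiral_pair"
  }
  name <- format_name(rep_state,
                      prefix = if (chirality == "chiral_pair") "D/L" else "none")
  structure(list(representative = rep_state,
                 partner = partner,
                 chirality = chirality,
                 display_name = name,
                 n_phosphates = length(rep_state$positions)),
            class = "isomer_class")
}

#' @export
print.isomer_class <- function(x, ...) {
  cat(x$display_name, " [", x$chirality, "]\n", sep = "")
  invisible(x)
}

#' Partition InsPn stereoisomers into achiral co-elution classes
#'
#' Groups all choose(6, n) phosphorylation patterns into the classes that are
#' indistinguishable on an achiral column: enantiomer pairs (size 2) and meso
#' singletons (size 1).
#'
#' @param n_phosphates integer in 0..6.
#' @return list of [canonical_class] objects, ordered lexicographically by
#'   representative.
#' @examples
#' length(coelution_partition(5))  # 4 classes: 2 meso + 2 enantiomer pairs
#' @export
coelution_partition <- function(n_phosphates) {
  states <- enumerate_isomers(n_phosphates)
  classes <- lapply(states, canonical_class)
  keys <- vapply(classes, function(cl) paste(cl$representative$positions, collapse = ","),
                 character(1))
  classes[!duplicated(keys)]
}

#' Filter states lacking a given locant
#'
#' Returns the sublist of states whose pattern does not contain `locant`
#' (e.g. the InsP4 patterns without a 2-phosphate), order preserved.
#'
#' @param states list of [phospho_state].
#' @param locant integer in 1..6.
#' @return filtered list.
#' @export
filter_lacking <- function(states, locant) {
  if (length(locant) != 1 || is.na(locant) || locant < 1 || locant > 6) {
    stop("locant must be a single integer in 1..6", call. = FALSE)
  }
  locant <- as.integer(locant)
  states[!vapply(states, function(s) locant %in% .assert_state(s)$positions,
                 logical(1))]
}

#' Format a phosphorylation state as an inositol phosphate name
#'
#' Produces names of the form `"D-Ins(1,2,3,4,5)P5"`, `"Ins(1,3,4,6)P4"`,
#' `"D/L-Ins(1,2,4,6)P4"`. Locants are printed ascending; the phosphate
#' count suffix equals the number of locants. Free inositol formats as
#' `"Ins"`.
#'
#' @param state a [phospho_state].
#' @param prefix one of `"auto"` (use the prefix the state was parsed with,
#'   else the state's numbering for chiral states and none for meso),
#'   `"none"`, `"D"`, `"L"`, `"D/L"`.
#' @return character name.
#' @export
format_name <- function(state, prefix = "auto") {
  state <- .assert_state(state)
  stopifnot(prefix %in% c("auto", "none", "D", "L", "D/L"))
  if (prefix == "auto") {
    stored <- attr(state, "prefix")
    prefix <- if (!is.null(stored)) stored
      else if (is_meso(state)) "none"
      else state$numbering
  }
  pre <- switch(prefix, none = "", D = "D-", L = "L-", `D/L` = "D/L-")
  n <- length(state$positions)
  if (n == 0L) return(paste0(pre, "Ins"))
  paste0(pre, "Ins(", paste(state$positions, collapse = ","), ")P", n)
}

#' Parse an inositol phosphate name
#'
#' Accepts names of the form `[D-|L-|D/L-]Ins(c1,c2,...)Pn` (and the
#' underscored variant `P_n`). The phosphate count must equal the number of
#' locants. A `D/L-` prefix denotes a co-elution class; the returned state is
#' the written member in D numbering with the prefix retained as an
#' attribute, so `parse_name(format_name(s))` round-trips.
#'
#' @param text a single name.
#' @return a [phospho_state] with attribute `prefix`.
#' @examples
#' parse_name("D-Ins(1,2,3,4,5)P5")
#' parse_name("Ins(1,3,4,6)P_4")
#' @export
parse_name <- function(text) {
  if (length(text) != 1 || !is.character(text)) {
    stop("parse error: expected a single character string", call. = FALSE)
  }
  txt <- trimws(text)
  if (txt %in% c("Ins", "D-Ins", "L-Ins", "D/L-Ins")) {
    pre <- sub("-?Ins$", "", txt)
    st <- phospho_state()
    attr(st, "prefix") <- if (pre == "") "none" else pre
    return(st)
  }
  m <- regexec("^(D/L-|D-|L-)?Ins\\(([0-9]+(?:[ ]*,[ ]*[0-9]+)*)\\)P_?([0-9]+)$",
               txt)
  g <- regmatches(txt, m)[[1]]
  if (length(g) == 0) {
    # locate first unexpected character for the error message
    ok <- regexpr("^(D/L-|D-|L-)?Ins\\(", txt)
    at <- if (ok == -1) 1L else attr(ok, "match.length") + 1L
    stop(sprintf("parse error in %s at position %d: expected [D-|L-|D/L-]Ins(locants)Pn",
                 sQuote(text), at), call. = FALSE)
  }
  pre_txt <- g[2]
  locants <- as.integer(strsplit(g[3], "[ ]*,[ ]*")[[1]])
  n_declared <- as.integer(g[4])
  bad <- which(locants < 1L | locants > 6L)
  if (length(bad)) {
    stop(sprintf("parse error in %s: locant %d out of range 1..6 (locant #%d)",
                 sQuote(text), locants[bad[1]], bad[1]), call. = FALSE)
  }
  if (anyDuplicated(locants)) {
    stop(sprintf("parse error in %s: duplicate locant", sQuote(text)), call. = FALSE)
  }
  if (length(locants) != n_declared) {
    stop(sprintf("parse error in %s: %d locants listed but phosphate count is %d",
                 sQuote(text), length(locants), n_declared), call. = FALSE)
  }
  prefix <- switch(pre_txt %||% "", "D-" = "D", "L-" = "L", "D/L-" = "D/L", "none")
  if (identical(pre_txt, "")) prefix <- "none"
  numbering <- if (prefix == "L") "L" else "D"
  st <- phospho_state(locants, numbering = numbering)
  attr(st, "prefix") <- prefix
  st
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' Tabulate the co-elution classes of InsPn
#'
#' @param n_phosphates integer in 0..6, or a vector of them.
#' @return data.frame with columns `display_name`, `members`
#'   (semicolon-joined member names), `chirality`, `n_phosphates`.
#' @export
class_table <- function(n_phosphates = 0:6) {
  rows <- lapply(n_phosphates, function(n) {
    cls <- coelution_partition(n)
    do.call(rbind, lapply(cls, function(cl) {
      members <- format_name(cl$representative, prefix = "none")
      if (cl$chirality == "chiral_pair") {
        members <- paste(members, format_name(cl$partner, prefix = "none"), sep = ";")
      }
      data.frame(display_name = cl$display_name, members = members,
                 chirality = cl$chirality, n_phosphates = cl$n_phosphates,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
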