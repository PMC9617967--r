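#' Lattice geometry configuration
#'
#' The microtubule is modeled as a two-dimensional sheet of protofilament
#' columns with periodic lateral boundaries.  The seam sits between the last
#' protofilament and the first: the last column is raised by `seam_offset`
#' (1.5) dimer units relative to the first, so contacts across the seam
#' contribute half lateral neighbors.
#'
#' @param n_protofilaments Number of protofilament columns (default 13; other
#'   values are supported mainly so that a 1-protofilament chain can be
#'   checked against closed-form birth-death results).
#' @param seam_offset Axial stagger across the seam, in dimer units.  Fixed
#'   at 1.5 by the lattice geometry; validated, not tunable.
#' @param start_length Initial dimers per column (default 10), present so
#'   dissociation is possible from the first step.
#' @param dimer_length Axial length of one alpha/beta-dimer in nm (default 8,
#'   the tubulin dimer repeat); only used to convert growth to um/s.
#' @return An object of class `lattice_config`.
#' @export
lattice_config <- function(n_protofilaments = 13, seam_offset = 1.5,
                           start_length = 10, dimer_length = 8) {
  stopifnot(n_protofilaments >= 1, start_length >= 0, dimer_length > 0)
  if (!identical(as.numeric(seam_offset), 1.5)) {
    stop("seam_offset is fixed at 1.5 dimer units", call. = FALSE)
  }
  structure(
    list(n_protofilaments = as.integer(n_protofilaments), seam_offset = 1.5,
         start_length = as.integer(start_length),
         dimer_length = as.numeric(dimer_length)),
    class = "lattice_config")
}

#' Create an empty or pre-seeded protofilament lattice
#'
#' Columns are gap-free sequences of species ids; height h of column p is
#' `lattice$columns[[p]][h]`.  The tip of column p is its last element and
#' the prospective binding site is one above it.
#'
#' @param config A [lattice_config()].
#' @param columns Optional list of integer vectors (species ids 1..3) used to
#'   pre-seed the columns; defaults to all columns empty.
#' @return An object of class `mt_lattice`.
#' @export
new_lattice <- function(config = lattice_config(), columns = NULL) {
  stopifnot(inherits(config, "lattice_config"))
  if (is.null(columns)) {
    columns <- rep(list(integer(0)), config$n_protofilaments)
  }
  if (length(columns) != config$n_protofilaments) {
    stop("`columns` must have one entry per protofilament", call. = FALSE)
  }
  columns <- lapply(columns, function(cl) {
    cl <- as.integer(cl)
    if (length(cl) && !all(cl %in% 1:3)) {
      stop("column entries must be species ids 1..3", call. = FALSE)
    }
    cl
  })
  structure(list(columns = columns, config = config), class = "mt_lattice")
}

#' @export
print.mt_lattice <- function(x, ...) {
  cat(sprintf("<mt_lattice> %d protofilaments, lengths: %s\n",
              x$config$n_protofilaments,
              paste(vapply(x$columns, length, integer(1)), collapse = " ")))
  invisible(x)
}

#' Per-protofilament column lengths
#'
#' @param lattice An `mt_lattice`.
#' @return Integer vector of dimer counts per column.
#' @export
column_lengths <- function(lattice) {
  vapply(lattice$columns, length, integer(1))
}

check_pf <- function(lattice, pf) {
  if (length(pf) != 1L || is.na(pf) || pf < 1 ||
      pf > lattice$config$n_protofilaments) {
    stop("protofilament index out of range", call. = FALSE)
  }
  as.integer(pf)
}

occupied_at <- function(lattice, pf, height) {
  n <- lattice$config$n_protofilaments
  if (pf < 1 || pf > n) return(FALSE)
  height >= 1 && height <= length(lattice$columns[[pf]])
}

#' Lateral neighbor count at a lattice site
#'
#' Counts the fractional occupancy overlap between the site (`pf`, `height`)
#' and the two laterally adjacent protofilaments.  Away from the seam an
#' occupied dimer at the same height on an adjacent column contributes 1.
#' Across the seam the 1.5-dimer stagger splits contacts: a site at height h
#' on the last protofilament half-overlaps heights h+1 and h+2 of
#' protofilament 1 (0.5 each), and a site at height h on protofilament 1
#' half-overlaps heights h-2 and h-1 of the last protofilament.  Possible
#' values are 0, 0.5, 1, 1.5 and 2.  The site itself need not be occupied
#' (prospective binding sites are queried at one above the tip).
#'
#' @param lattice An `mt_lattice`.
#' @param pf Protofilament index (1-based).
#' @param height Dimer height (1-based, >= 1).
#' @return Lateral neighbor count x in \{0, 0.5, 1, 1.5, 2\}.
#' @export
lateral_neighbor_count <- function(lattice, pf, height) {
  pf <- check_pf(lattice, pf)
  if (length(height) != 1L || is.na(height) || height < 1) {
    stop("height must be >= 1", call. = FALSE)
  }
  n <- lattice$config$n_protofilaments
  if (n == 1L) return(0)
  x <- 0
  # left edge (between pf-1 and pf)
  if (pf == 1L) {
    q <- n  # seam: neighbor column is raised by +1.5
    x <- x + 0.5 * occupied_at(lattice, q, height - 2) +
      0.5 * occupied_at(lattice, q, height - 1)
  } else {
    x <- x + 1 * occupied_at(lattice, pf - 1L, height)
  }
  # right edge (between pf and pf+1)
  if (pf == n) {
    q <- 1L  # seam: this column is raised by +1.5 relative to column 1
    x <- x + 0.5 * occupied_at(lattice, q, height + 1) +
      0.5 * occupied_at(lattice, q, height + 2)
  } else {
    x <- x + 1 * occupied_at(lattice, pf + 1L, height)
  }
  x
}

#' Append a dimer to a protofilament tip
#'
#' @param lattice An `mt_lattice`.
#' @param pf Protofilament index.
#' @param species Species id (1..3) of the added dimer.
#' @return The updated lattice (columns stay gap-free by construction).
#' @export
add_dimer <- function(lattice, pf, species) {
  pf <- check_pf(lattice, pf)
  if (length(species) != 1L || !(species %in% 1:3)) {
    stop("unknown species id", call. = FALSE)
  }
  lattice$columns[[pf]] <- c(lattice$columns[[pf]], as.integer(species))
  lattice
}

#' Heights removed by a cascade (stack) dissociation
#'
#' When a dimer dissociates from inside the lattice, every dimer above it on
#' the same protofilament leaves with it.
#'
#' @param lattice An `mt_lattice`.
#' @param pf Protofilament index.
#' @param height Occupied height of the departing stack's bottom dimer.
#' @return Integer vector of removed heights, `height:L_p`.
#' @export
cascade_removal_set <- function(lattice, pf, height) {
  pf <- check_pf(lattice, pf)
  L <- length(lattice$columns[[pf]])
  if (length(height) != 1L || is.na(height) || height < 1 || height > L) {
    stop("height is not occupied", call. = FALSE)
  }
  seq.int(as.integer(height), L)
}

#' Apply a cascade dissociation
#'
#' Truncates column `pf` to length `height - 1`.
#'
#' @inheritParams cascade_removal_set
#' @return The updated lattice.
#' @export
remove_cascade <- function(lattice, pf, height) {
  hs <- cascade_removal_set(lattice, pf, height)  # validates
  pf <- as.integer(pf)
  lattice$columns[[pf]] <- lattice$columns[[pf]][seq_len(hs[1] - 1L)]
  lattice
}

# internal invariant check used by property tests: every column is a plain
# integer vector of species ids with no gaps (by representation) and valid ids
lattice_is_valid <- function(lattice) {
  all(vapply(lattice$columns, function(cl) {
    is.integer(cl) && (!length(cl) || all(cl %in% 1:3))
  }, logical(1)))
}
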