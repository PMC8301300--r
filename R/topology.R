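# Lattice geometry and E/I connectivity.
#
# Excitatory neurons sit on the integer sites of an e_side x e_side square
# lattice with periodic boundaries; inhibitory neurons sit at the plaquette
# centers of a spacing-2 superlattice, offset (0.5, 0.5) from the E sites.
# This is the unique simple geometry in which circular cutoffs around each I
# select exactly 12 E targets (squared distance < 4.5, the 0.5 and 2.5
# shells) and exactly 32 E sources (squared distance <= 8.5).

.INNER_D2 <- 4.5   # strict: shells d2 = 0.5 (x4) and 2.5 (x8) -> 12 sites
.OUTER_D2 <- 8.5   # inclusive: adds d2 = 4.5 (x4), 6.5 (x8), 8.5 (x8) -> 32

#' Build the periodic excitatory/inhibitory lattice
#'
#' Excitatory (E) neurons occupy every integer site of an `e_side` x `e_side`
#' periodic square lattice; inhibitory (I) neurons occupy the plaquette
#' centers of a spacing-2 superlattice (offset 0.5, 0.5 in E-lattice units),
#' giving the 4:1 E:I count of a balanced cortical module.
#'
#' @param e_side Even integer >= 6; number of E neurons per lattice side.
#' @return An object of class `lattice_spec`: a list with `e_side`, `n_e`,
#'   `n_i`, and the 2-D coordinates `positions_e`, `positions_i` (matrices,
#'   E-lattice units; neurons indexed row-major, 1-based).
#' @examples
#' lat <- build_lattice(14)   # 196 E, 49 I
#' @export
build_lattice <- function(e_side) {
  if (length(e_side) != 1L || !is.finite(e_side) || e_side != round(e_side))
    stop("e_side must be a single integer")
  e_side <- as.integer(e_side)
  if (e_side %% 2L != 0L)
    stop("e_side must be even (I neurons sit on a spacing-2 superlattice)")
  if (e_side < 6L)
    stop("e_side must be >= 6: the 32-source neighborhood would wrap onto itself")
  n_e <- e_side^2L
  i_side <- e_side %/% 2L
  n_i <- i_side^2L
  # row-major: index = iy * side + ix + 1
  ix <- rep(seq_len(e_side) - 1L, times = e_side)
  iy <- rep(seq_len(e_side) - 1L, each = e_side)
  jx <- rep(seq_len(i_side) - 1L, times = i_side)
  jy <- rep(seq_len(i_side) - 1L, each = i_side)
  structure(list(
    e_side = e_side, n_e = n_e, n_i = n_i,
    positions_e = cbind(x = ix, y = iy),
    positions_i = cbind(x = 2 * jx + 0.5, y = 2 * jy + 0.5)
  ), class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("Periodic E/I lattice: %d x %d, %d E neurons, %d I neurons\n",
              x$e_side, x$e_side, x$n_e, x$n_i))
  invisible(x)
}

# E-site indices (1-based, row-major) within squared periodic distance d2max
# of I neuron i_index's plaquette center.  Ordered row-major by offset so the
# edge lists are identical (up to translation) for every I.
.neighborhood <- function(lattice, i_index, d2max, strict = FALSE) {
  stopifnot(i_index >= 1L, i_index <= lattice$n_i)
  L <- lattice$e_side
  i_side <- L %/% 2L
  jx <- (i_index - 1L) %% i_side
  jy <- (i_index - 1L) %/% i_side
  cx <- 2L * jx        # E site just below-left of the center (cx + 0.5, cy + 0.5)
  cy <- 2L * jy
  off <- -3:4          # offsets from (cx, cy); |offset - 0.5| <= 3 covers d2 <= 8.5
  ox <- rep(off, times = length(off))
  oy <- rep(off, each = length(off))
  d2 <- (ox - 0.5)^2 + (oy - 0.5)^2
  keep <- if (strict) d2 < d2max else d2 <= d2max
  ex <- (cx + ox[keep]) %% L
  ey <- (cy + oy[keep]) %% L
  as.integer(ey * L + ex + 1L)
}

#' Inhibitory projection neighborhood (12 E targets)
#'
#' The 12 E neurons within the inner circle around an I neuron's plaquette
#' center (squared periodic distance < 4.5 E-lattice units); these receive
#' the I neuron's inhibitory synapses.
#'
#' @param lattice A `lattice_spec`.
#' @param i_index I-neuron index (1-based, row-major on the superlattice).
#' @return Integer vector of 12 E indices.
#' @export
inner_neighborhood <- function(lattice, i_index)
  .neighborhood(lattice, i_index, .INNER_D2, strict = TRUE)

#' Excitatory source neighborhood (32 E sources)
#'
#' The 32 E neurons within the outer circle (squared periodic distance
#' <= 8.5) around an I neuron; these excite it.  Superset of
#' [inner_neighborhood()].
#'
#' @inheritParams inner_neighborhood
#' @return Integer vector of 32 E indices.
#' @export
outer_neighborhood <- function(lattice, i_index)
  .neighborhood(lattice, i_index, .OUTER_D2, strict = FALSE)

#' Build the full I->E / E->I connectivity map
#'
#' Each I neuron inhibits its 12 inner-circle E neurons and is excited by its
#' 32 outer-circle E neurons.  There are no E-E or I-I connections.
#'
#' @param lattice A `lattice_spec`.
#' @return An object of class `connectivity_map`: list with `i_to_e`
#'   (`n_i` x 12 integer matrix of E targets), `e_to_i` (`n_i` x 32 integer
#'   matrix of E sources), `pr` (rewiring probability used, 0 here),
#'   `e_side`, and `lattice`.
#' @export
build_connectivity <- function(lattice) {
  stopifnot(inherits(lattice, "lattice_spec"))
  i_to_e <- t(vapply(seq_len(lattice$n_i),
                     function(i) inner_neighborhood(lattice, i), integer(12)))
  e_to_i <- t(vapply(seq_len(lattice$n_i),
                     function(i) outer_neighborhood(lattice, i), integer(32)))
  structure(list(i_to_e = i_to_e, e_to_i = e_to_i, pr = 0,
                 e_side = lattice$e_side, lattice = lattice),
            class = "connectivity_map")
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat(sprintf(
    "E/I connectivity: %d I neurons, %d I->E edges, %d E->I edges (pr = %g)\n",
    nrow(x$i_to_e), length(x$i_to_e), length(x$e_to_i), x$pr))
  invisible(x)
}

# run expr under a private RNG stream seeded with `seed`, restoring the
# caller's stream afterwards
.with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Small-world rewiring of the connectivity map
#'
#' Each I->E edge is independently replaced with probability `pr` by an edge
#' to an E neuron drawn uniformly among those not already targeted by that I;
#' each E->I edge is re-sourced analogously.  Degrees (12 targets, 32
#' sources per I) are preserved and duplicate edges never arise.
#'
#' @param conn A `connectivity_map`.
#' @param pr Rewiring probability in \[0, 1\].
#' @param seed Integer seed; the map is deterministic given (`conn`, `pr`,
#'   `seed`).
#' @return A rewired `connectivity_map` with `pr` recorded.
#' @export
rewire <- function(conn, pr, seed) {
  stopifnot(inherits(conn, "connectivity_map"),
            length(pr) == 1L, pr >= 0, pr <= 1)
  if (pr == 0) {
    conn$pr <- 0
    return(conn)
  }
  n_e <- conn$e_side^2L
  rewire_row <- function(row) {
    hit <- runif(length(row)) < pr
    for (k in which(hit)) {
      pool <- setdiff(seq_len(n_e), row)
      row[k] <- pool[floor(runif(1) * length(pool)) + 1L]
    }
    row
  }
  .with_seed(seed, {
    for (i in seq_len(nrow(conn$i_to_e)))
      conn$i_to_e[i, ] <- rewire_row(conn$i_to_e[i, ])
    for (i in seq_len(nrow(conn$e_to_i)))
      conn$e_to_i[i, ] <- rewire_row(conn$e_to_i[i, ])
  })
  conn$pr <- pr
  conn
}

#' Write / read a connectivity map as an edge-list text file
#'
#' Plain-text format: a first line `# {json}` holding `e_side`, `pr` and an
#' optional `seed`, followed by a CSV edge list with columns `source_type`,
#' `source_index`, `target_type`, `target_index` (1-based indices; `E->I`
#' rows are the excitatory source edges, `I->E` rows the inhibitory target
#' edges).
#'
#' @param conn A `connectivity_map`.
#' @param path Output file path.
#' @param seed Optional integer recorded in the header.
#' @return `write_connectivity` returns `path` invisibly;
#'   `read_connectivity` returns the reconstructed `connectivity_map`.
#' @export
write_connectivity <- function(conn, path, seed = NULL) {
  stopifnot(inherits(conn, "connectivity_map"))
  hdr <- list(e_side = conn$e_side, pr = conn$pr)
  if (!is.null(seed)) hdr$seed <- seed
  n_i <- nrow(conn$i_to_e)
  edges <- rbind(
    data.frame(source_type = "I",
               source_index = rep(seq_len(n_i), each = ncol(conn$i_to_e)),
               target_type = "E",
               target_index = as.integer(t(conn$i_to_e))),
    data.frame(source_type = "E",
               source_index = as.integer(t(conn$e_to_i)),
               target_type = "I",
               target_index = rep(seq_len(n_i), each = ncol(conn$e_to_i)))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(hdr, auto_unbox = TRUE)), con)
  write.csv(edges, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  lines <- readLines(path, n = 1L)
  if (!startsWith(lines[1], "# "))
    stop("missing JSON header line in connectivity file")
  hdr <- jsonlite::fromJSON(sub("^# ", "", lines[1]))
  edges <- read.csv(path, skip = 1L, stringsAsFactors = FALSE)
  need <- c("source_type", "source_index", "target_type", "target_index")
  if (!all(need %in% names(edges)))
    stop("connectivity file must have columns: ", paste(need, collapse = ", "))
  lattice <- build_lattice(hdr$e_side)
  ie <- edges[edges$source_type == "I", ]
  ei <- edges[edges$target_type == "I", ]
  i_to_e <- matrix(ie$target_index[order(ie$source_index)],
                   nrow = lattice$n_i, byrow = TRUE)
  # preserve within-I order: order() is stable so rows keep file order
  e_to_i <- matrix(ei$source_index[order(ei$target_index)],
                   nrow = lattice$n_i, byrow = TRUE)
  if (ncol(i_to_e) != 12L || ncol(e_to_i) != 32L)
    stop("edge counts are not 12 targets / 32 sources per I neuron")
  structure(list(i_to_e = i_to_e, e_to_i = e_to_i, pr = hdr$pr,
                 e_side = hdr$e_side, lattice = lattice),
            class = "connectivity_map")
}
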