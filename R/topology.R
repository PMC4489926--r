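#' Closed polygon constructor
#'
#' An ordered list of 3D vertices representing a circular chain; the
#' closing edge from the last vertex back to the first is implicit.
#' Optionally carries the (1-based) positions of the two internal sticky
#' beads, needed by the loop-relevance analysis.
#'
#' @param vertices M x 3 matrix, M >= 3.
#' @param marked optional length-2 integer vector of marked vertex
#'   positions (internal sticky pair), strictly increasing.
#' @return an object of class \code{closed_polygon}.
#' @export
closed_polygon <- function(vertices, marked = NULL) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 3, nrow(vertices) >= 3)
  m <- nrow(vertices)
  nxt <- c(2:m, 1)
  if (any(sqrt(rowSums((vertices - vertices[nxt, , drop = FALSE])^2)) < 1e-12))
    stop("consecutive vertices coincide")
  if (!is.null(marked)) {
    marked <- as.integer(marked)
    stopifnot(length(marked) == 2, marked[1] < marked[2],
              marked[1] >= 1, marked[2] <= m)
  }
  structure(list(vertices = vertices, marked = marked),
            class = "closed_polygon")
}

#' Close a circularized run into a polygon
#'
#' The simulation protocol terminates at the circularization event, so
#' the final frame is already a closed ring: the polygon is simply the
#' bead positions in chain order, with the terminal adhesion bond
#' providing the closing edge.  No auxiliary closure arc is constructed.
#' Internal sticky bead positions are carried over as marks.
#'
#' @param outcome a \code{run_outcome} with \code{circularized = TRUE}.
#' @return a \code{closed_polygon}.
#' @export
close_chain <- function(outcome) {
  if (!isTRUE(outcome$circularized))
    stop("topology undefined: run was censored (no circularization)")
  closed_polygon(outcome$final_positions,
                 marked = outcome$params$sticky_internal_pair)
}

#' Geometric chain simplification
#'
#' Repeatedly removes a vertex whose adjacent triangle is pierced by no
#' other edge of the polygon (an ambient isotopy, preserving the knot
#' type) until no further removal applies.  Marked vertices are never
#' removed when \code{protect_marks} is set, so the sticky-loop
#' decomposition stays available on the reduced polygon.
#'
#' @param poly a \code{closed_polygon}.
#' @param protect_marks keep the marked vertices (default when marks are
#'   present).
#' @return the reduced \code{closed_polygon}.
#' @export
kmt_simplify <- function(poly, protect_marks = !is.null(poly$marked)) {
  prot <- if (protect_marks && !is.null(poly$marked)) poly$marked
          else integer(0)
  res <- cpp_kmt(poly$vertices, as.integer(prot))
  marked <- NULL
  if (protect_marks && !is.null(poly$marked))
    marked <- match(poly$marked, res$kept)
  closed_polygon(res$vertices, marked = marked)
}

#' Alexander determinants of a closed polygon
#'
#' Projects the polygon onto a random plane, extracts the crossing
#' diagram, and evaluates the Alexander polynomial at t = -1 and t = -2.
#' The power-of-t ambiguity of the Alexander-matrix determinant is
#' removed exactly by sampling the determinant on the complex unit
#' circle and reconstructing \eqn{\Delta(t)\Delta(1/t)} by a discrete
#' Fourier transform, so the returned pair is projection independent.
#' Degenerate projections are retried with a fresh random rotation.
#'
#' @param poly a \code{closed_polygon} (or an M x 3 vertex matrix).
#' @param max_tries maximum number of projection attempts.
#' @param seed seed of the projection rotations.
#' @return integer vector \code{c(det_minus1, det_minus2)}; both -1 when
#'   the polynomial is too large to reconstruct exactly (classified
#'   "other" downstream).
#' @export
alexander_determinants <- function(poly, max_tries = 50, seed = 1) {
  v <- if (inherits(poly, "closed_polygon")) poly$vertices else poly
  res <- cpp_alexander(v, as.integer(max_tries), as.double(seed))
  c(det_minus1 = res$det_minus1, det_minus2 = res$det_minus2)
}

# determinant pair -> knot label lookup
knot_det_table <- data.frame(
  label = c("0_1", "3_1", "4_1", "5_1", "5_2"),
  det_minus1 = c(1, 3, 5, 5, 7),
  det_minus2 = c(1, 7, 11, 31, 16),
  stringsAsFactors = FALSE)

#' Classify a knot from its Alexander determinants
#'
#' Deterministic table lookup on \code{(|Delta(-1)|, |Delta(-2)|)}:
#' (1,1) unknot, (3,7) trefoil, (5,11) figure-eight, (5,31) 5_1,
#' (7,16) 5_2; any other pair maps to \code{"other"}.  The pair
#' separates every knot type reported by the pipeline; chirality is not
#' resolved (the Alexander polynomial cannot see it).
#'
#' @param dets numeric vector \code{c(det_minus1, det_minus2)}.
#' @return a character label.
#' @export
classify_knot <- function(dets) {
  hit <- knot_det_table$det_minus1 == dets[1] &
         knot_det_table$det_minus2 == dets[2]
  if (any(hit)) knot_det_table$label[which(hit)[1]] else "other"
}

#' Full classification pipeline for a polygon
#'
#' Simplifies geometrically, then computes Alexander determinants and
#' the knot label.
#'
#' @inheritParams alexander_determinants
#' @param simplify reduce the polygon first (recommended; the
#'   determinant cost grows quickly with the crossing number).
#' @return list with \code{label}, \code{det_minus1}, \code{det_minus2}.
#' @export
classify_polygon <- function(poly, simplify = TRUE, max_tries = 50, seed = 1) {
  if (!inherits(poly, "closed_polygon")) poly <- closed_polygon(poly)
  if (simplify) poly <- kmt_simplify(poly, protect_marks = FALSE)
  d <- alexander_determinants(poly, max_tries = max_tries, seed = seed)
  list(label = classify_knot(d), det_minus1 = unname(d[1]),
       det_minus2 = unname(d[2]))
}

#' Was the sticky loop closed at the end of a run?
#'
#' True iff the internal adhesion flag was set when the run terminated;
#' equivalent to the internal pair sitting within the capture distance
#' in the final frame (adhesion is permanent).
#'
#' @param outcome a circularized \code{run_outcome}.
#' @param params,protocol the run's model parameters and protocol.
#' @return logical flag.
#' @export
loop_closed <- function(outcome, params = outcome$params, protocol = NULL) {
  if (!isTRUE(outcome$circularized))
    stop("loop closure is reported for circularized runs only")
  isTRUE(outcome$internal_loop_closed_at_end)
}

#' Topological relevance of a closed sticky loop
#'
#' Implements the loop-excision test: from the marked polygon build (a)
#' the excised ring, i.e. the chain outside the sticky loop with a
#' direct edge bridging the two sticky beads, and (b) the sticky-loop
#' ring, i.e. the loop segment closed by the same direct edge.  The
#' loop is \emph{irrelevant} when the knot is completely localized in
#' one of the two sub-rings: either the excised ring still carries the
#' full knot type (knot in the complementary loop), or the sticky-loop
#' ring carries it while the excised ring is unknotted (knot tied
#' inside the loop).  In every other case the loop and the knot are
#' entangled and the loop is \emph{relevant}.  Because the sticky pair
#' is adhered (within the capture distance) the direct closing edge is
#' short and cannot introduce spurious entanglement at that scale.
#'
#' @param poly a marked \code{closed_polygon}.
#' @param knot_full the knot label of the full ring (must not be the
#'   unknot).
#' @param seed projection seed forwarded to classification.
#' @return \code{"relevant"} or \code{"irrelevant"}, with attribute
#'   \code{sub_labels} giving the two sub-ring labels.
#' @export
loop_relevance <- function(poly, knot_full, seed = 1) {
  if (is.list(knot_full)) knot_full <- knot_full$label
  if (identical(knot_full, "0_1"))
    stop("loop relevance is defined for knotted chains only")
  if (is.null(poly$marked)) stop("polygon carries no sticky-loop marks")
  m <- nrow(poly$vertices)
  mx <- poly$marked[1]; my <- poly$marked[2]
  excised_idx <- c(seq_len(mx), my:m)
  loop_idx <- mx:my
  class_of <- function(idx) {
    if (length(idx) < 3) return("0_1")
    classify_polygon(poly$vertices[idx, , drop = FALSE], seed = seed)$label
  }
  excised <- class_of(excised_idx)
  if (identical(excised, knot_full)) # knot sits in the complementary loop
    return(structure("irrelevant",
                     sub_labels = c(excised = excised, loop = NA)))
  loop_lab <- class_of(loop_idx)
  if (identical(loop_lab, knot_full) && identical(excised, "0_1"))
    return(structure("irrelevant", # knot tied inside the sticky loop
                     sub_labels = c(excised = excised, loop = loop_lab)))
  structure("relevant", sub_labels = c(excised = excised, loop = loop_lab))
}

# ---- fixtures -----------------------------------------------------------

# minimal crossing number per label, for the vertex-count precondition
knot_crossing_number <- c("0_1" = 0, "3_1" = 3, "4_1" = 4, "5_1" = 5,
                          "5_2" = 5)

# polygonal closure of a braid word on `strands` strands; positive letter
# i crosses strand i over i+1.  Returns a vertex matrix tracing the
# closure as a single cycle (errors if the closure is a multi-component
# link).
braid_closure <- function(word, strands) {
  w <- length(word)
  paths <- lapply(seq_len(strands), function(s)
    matrix(c(s, 0, 0), ncol = 3))
  posn <- seq_len(strands) # posn[k]: current position of path k
  for (j in seq_along(word)) {
    i <- abs(word[j])
    over_first <- word[j] > 0
    a <- which(posn == i); b <- which(posn == i + 1)
    za <- if (over_first) 0.5 else -0.5
    paths[[a]] <- rbind(paths[[a]], c(i + 0.5, j - 0.5, za),
                        c(i + 1, j, 0))
    paths[[b]] <- rbind(paths[[b]], c(i + 0.5, j - 0.5, -za),
                        c(i, j, 0))
    posn[a] <- i + 1; posn[b] <- i
    for (k in seq_len(strands)[-c(a, b)])
      paths[[k]] <- rbind(paths[[k]], c(posn[k], j, 0))
  }
  # closure arcs: from bottom of position q around the right side back to
  # the top of position q; nested rectangles, no mutual crossings
  perm <- posn # path k (which started at position k) ends at position perm[k]
  cyc <- integer(0); cur <- 1L
  repeat {
    cyc <- c(cyc, cur)
    nxt <- perm[cur]                     # path cur ends at position nxt
    if (nxt == 1L) break
    cur <- nxt
    if (length(cyc) > strands) stop("braid closure is not a single cycle")
  }
  if (length(cyc) != strands)
    stop("braid closure is a link, not a knot")
  verts <- NULL
  for (k in cyc) {
    q <- perm[k]
    a <- 0.5 + 0.5 * q
    zq <- -(1 + 0.4 * q) # each return arc at its own depth
    arc <- rbind(c(q, w + a, 0),
                 c(q, w + a, zq),
                 c(strands + q, w + a, zq),
                 c(strands + q, -a, zq),
                 c(q, -a, zq),
                 c(q, -a, 0))
    verts <- rbind(verts, paths[[k]], arc)
  }
  verts
}

# subdivide polygon edges (longest first) until it has n vertices
subdivide_to <- function(v, n) {
  while (nrow(v) < n) {
    m <- nrow(v)
    nxt <- c(2:m, 1)
    len <- sqrt(rowSums((v[nxt, , drop = FALSE] - v)^2))
    i <- which.max(len)
    mid <- (v[i, ] + v[if (i == m) 1 else i + 1, ]) / 2
    v <- if (i == m) rbind(v, mid)
         else rbind(v[1:i, , drop = FALSE], mid,
                    v[(i + 1):m, , drop = FALSE])
  }
  v
}

#' Parametric knot fixtures
#'
#' Generates closed polygonal curves of known knot type for validating
#' the topology pipeline: a circle (unknot), the (2,3) and (2,5) torus
#' knots (trefoil, 5_1), the standard figure-eight curve, and the
#' three-half-twist twist knot (5_2) built as a polygonal braid closure.
#' Bounded uniform vertex jitter of amplitude \code{noise_amplitude}
#' (in curve units, well below the strand separation) can be added.
#'
#' @param label one of \code{"0_1"}, \code{"3_1"}, \code{"4_1"},
#'   \code{"5_1"}, \code{"5_2"}.
#' @param n_vertices number of polygon vertices; at least three times
#'   the minimal crossing number.
#' @param noise_amplitude uniform jitter half-width.
#' @param seed RNG seed for the jitter.
#' @return a \code{closed_polygon} whose knot type equals \code{label}.
#' @export
parametric_knot <- function(label, n_vertices = 200, noise_amplitude = 0,
                            seed = 1) {
  label <- match.arg(label, names(knot_crossing_number))
  need <- max(3, 3 * knot_crossing_number[[label]])
  if (n_vertices < need)
    stop(sprintf("need at least %d vertices for %s", need, label))
  t <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  v <- switch(label,
    "0_1" = cbind(2 * cos(t), 2 * sin(t), 0 * t),
    "3_1" = cbind((2 + cos(3 * t)) * cos(2 * t),
                  (2 + cos(3 * t)) * sin(2 * t), sin(3 * t)),
    "5_1" = cbind((2 + cos(5 * t)) * cos(2 * t),
                  (2 + cos(5 * t)) * sin(2 * t), sin(5 * t)),
    "4_1" = cbind((2 + cos(2 * t)) * cos(3 * t),
                  (2 + cos(2 * t)) * sin(3 * t), sin(4 * t)),
    "5_2" = subdivide_to(braid_closure(c(1, 1, 1, 2, -1, 2), 3),
                         n_vertices))
  if (noise_amplitude > 0) {
    v <- v + with_seed_local(seed, matrix(
      runif(3 * nrow(v), -noise_amplitude, noise_amplitude), ncol = 3))
  }
  closed_polygon(v)
}

#' Random closed polygon
#'
#' Gaussian random-walk steps normalized to unit length, with the
#' closure defect spread uniformly over the steps; a standard source of
#' knotted test rings (no excluded volume, so knots are common already
#' at modest length).
#'
#' @param n number of vertices.
#' @param seed RNG seed.
#' @return a \code{closed_polygon}.
#' @export
random_closed_polygon <- function(n, seed = 1) {
  with_seed_local(seed, {
    st <- matrix(rnorm(3 * n), ncol = 3)
    st <- st / sqrt(rowSums(st^2))
    st <- sweep(st, 2, colMeans(st))
    closed_polygon(apply(st, 2, cumsum))
  })
}
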