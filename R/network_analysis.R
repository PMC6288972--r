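segment_signature <- function(g, schedule, morphogen, params, fitness) {
  dev <- develop(g, schedule, morphogen, params, noise_model(0))
  pat <- average_segmentation_expression(dev, schedule$control_period)
  rep_ <- call_segments(pat$mean, fitness)
  list(n_good = rep_$n_good, boundaries = rep_$boundaries)
}

#' Prune a genome to its core
#'
#' Repeatedly tries to remove genes (whole, with their sites) and then
#' individual binding sites, in genome order, re-developing the candidate
#' (noise off) after each tentative removal and keeping it only if the
#' segmentation pattern is preserved. Passes repeat until a full pass
#' removes nothing, so pruning is idempotent. The default preservation
#' criterion requires the same number of well-formed segments AND the same
#' boundaries within +/- `tol_cells` cells; `criterion = "count"` relaxes
#' this to the segment count alone.
#'
#' @param g a `cw_genome`.
#' @param schedule,morphogen,params,fitness the developmental and scoring
#'   conditions under which the pattern must be preserved.
#' @param criterion `"pattern"` (count + boundary positions) or `"count"`.
#' @param tol_cells boundary position tolerance in cells.
#' @return A `cw_pruned`: list with `genome` (the core), `removed`
#'   (descriptions of removed elements, in removal order) and `reference`
#'   (the preserved segment signature).
#' @export
prune_genome <- function(g, schedule = dev_schedule(),
                         morphogen = morphogen_config(),
                         params = kinetic_params(),
                         fitness = fitness_params(),
                         criterion = c("pattern", "count"),
                         tol_cells = 1) {
  criterion <- match.arg(criterion)
  ref <- segment_signature(g, schedule, morphogen, params, fitness)
  preserved <- function(cand) {
    sig <- segment_signature(cand, schedule, morphogen, params, fitness)
    if (sig$n_good != ref$n_good) return(FALSE)
    if (criterion == "count") return(TRUE)
    length(sig$boundaries) == length(ref$boundaries) &&
      all(abs(sig$boundaries - ref$boundaries) <= tol_cells)
  }

  cur <- g
  removed <- character(0)
  repeat {
    changed <- FALSE
    i <- 1L
    while (i <= length(cur$genes)) {
      cand <- cur
      cand$genes[[i]] <- NULL
      if (preserved(cand)) {
        removed <- c(removed, sprintf("gene %d (position %d)",
                                      cur$genes[[i]]$type, i))
        cur <- cand
        changed <- TRUE
      } else i <- i + 1L
    }
    i <- 1L
    while (i <= length(cur$genes)) {
      j <- 1L
      while (j <= nrow(cur$genes[[i]]$sites)) {
        cand <- cur
        cand$genes[[i]]$sites <- cand$genes[[i]]$sites[-j, , drop = FALSE]
        if (preserved(cand)) {
          removed <- c(removed,
                       sprintf("TFBS (%d,%+d) of gene %d (position %d)",
                               cur$genes[[i]]$sites[j, 1],
                               cur$genes[[i]]$sites[j, 2],
                               cur$genes[[i]]$type, i))
          cur <- cand
          changed <- TRUE
        } else j <- j + 1L
      }
      i <- i + 1L
    }
    if (!changed) break
  }
  structure(list(genome = cur, removed = removed, reference = ref),
            class = "cw_pruned")
}

#' @export
print.cw_pruned <- function(x, ...) {
  cat(sprintf("<cw_pruned> core: %d genes, %d TFBS (%d elements removed); preserves %d segments\n",
              n_genes(x$genome), n_tfbs(x$genome), length(x$removed),
              x$reference$n_good))
  invisible(x)
}

# Collapse the edge list to distinct (source, target, weight) arcs; sites
# duplicated with identical source, sign and target count once, while
# antagonistic parallel arcs stay distinct.
collapsed_arcs <- function(net) {
  unique(net$edges[, c("source", "target", "weight")])
}

#' Enumerate signed feedback loops
#'
#' All simple directed cycles of the type-level regulatory graph, with the
#' loop sign given by the product of edge weights along the cycle.
#' Self-loops are size-1 cycles. Where both an activating and a repressing
#' arc connect the same ordered node pair, each sign combination counts as
#' a distinct loop. Enumeration is a depth-first search rooted at each
#' node in ascending order (visiting only larger nodes), so every cycle is
#' found exactly once regardless of traversal direction.
#'
#' @param net a `cw_network` (see [build_network()]).
#' @param max_loops stop after this many loops; the result is then flagged
#'   truncated.
#' @return data.frame with one row per loop: `size`, `sign` and `members`
#'   (node types along the cycle, starting at its smallest node). The
#'   attribute `truncated` is `TRUE` if the cap was hit.
#' @export
enumerate_feedback_loops <- function(net, max_loops = 1e5) {
  arcs <- collapsed_arcs(net)
  nodes <- sort(unique(c(arcs$source, arcs$target)))
  # adjacency with per-arc sign sets
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    to <- arcs[arcs$source == v, ]
    split(to$weight, to$target)
  })
  out_size <- integer(0); out_sign <- integer(0); out_members <- character(0)
  truncated <- FALSE

  emit <- function(path) {
    # expand the sign choices of every arc along the node cycle
    k <- length(path)
    sets <- vector("list", k)
    for (i in seq_len(k)) {
      nxt <- if (i < k) path[i + 1] else path[1]
      sets[[i]] <- adj[[as.character(path[i])]][[as.character(nxt)]]
    }
    combos <- expand.grid(sets)
    for (r in seq_len(nrow(combos))) {
      if (length(out_size) >= max_loops) { truncated <<- TRUE; return(FALSE) }
      out_size <<- c(out_size, k)
      out_sign <<- c(out_sign, prod(as.numeric(combos[r, ])))
      out_members <<- c(out_members, paste(path, collapse = ">"))
    }
    TRUE
  }

  for (start in nodes) {
    onpath <- c()
    dfs <- function(v, path) {
      targets <- as.integer(names(adj[[as.character(v)]]))
      for (w in targets) {
        if (truncated) return()
        if (w == start) {
          if (!emit(path)) return()
        } else if (w > start && !(w %in% path)) {
          dfs(w, c(path, w))
        }
      }
    }
    dfs(start, start)
    if (truncated) break
  }
  res <- data.frame(size = out_size, sign = as.integer(out_sign),
                    members = out_members, stringsAsFactors = FALSE)
  attr(res, "truncated") <- truncated
  res
}

#' Network complexity report
#'
#' Genome size and loop census of a (typically pruned) genome: gene and
#' TFBS counts, positive/negative feedback-loop counts, the feedback-loop
#' size histogram and the number of feed-forward loops (ordered node
#' triples X->Y->Z with the shortcut X->Z, counted once per triple
#' irrespective of arc signs).
#'
#' @param x a `cw_pruned` or a `cw_genome`.
#' @param max_loops cap passed to [enumerate_feedback_loops()].
#' @return A `cw_complexity`: list with `n_genes`, `n_tfbs`, `n_pos_fbl`,
#'   `n_neg_fbl`, `loop_size_histogram` (named count vector over FBL
#'   sizes), `n_ffl` and the `loops` data.frame.
#' @export
complexity_report <- function(x, max_loops = 1e5) {
  g <- if (inherits(x, "cw_pruned")) x$genome else x
  net <- build_network(g)
  loops <- enumerate_feedback_loops(net, max_loops)
  arcs <- collapsed_arcs(net)
  n_ffl <- 0L
  if (nrow(arcs) > 0) {
    A <- matrix(FALSE, 16, 16)
    A[cbind(arcs$source + 1, arcs$target + 1)] <- TRUE
    nodes <- which(apply(A, 1, any) | apply(A, 2, any))
    for (x_ in nodes) for (y in nodes) for (z in nodes) {
      if (x_ != y && y != z && x_ != z &&
          A[x_, y] && A[y, z] && A[x_, z])
        n_ffl <- n_ffl + 1L
    }
  }
  sizes <- table(factor(loops$size, levels = sort(unique(loops$size))))
  structure(list(n_genes = n_genes(g), n_tfbs = n_tfbs(g),
                 n_pos_fbl = sum(loops$sign > 0),
                 n_neg_fbl = sum(loops$sign < 0),
                 loop_size_histogram = sizes,
                 n_ffl = n_ffl, loops = loops),
            class = "cw_complexity")
}

#' @export
print.cw_complexity <- function(x, ...) {
  cat(sprintf("<cw_complexity> %d genes, %d TFBS; FBL: %d positive, %d negative; %d FFL\n",
              x$n_genes, x$n_tfbs, x$n_pos_fbl, x$n_neg_fbl, x$n_ffl))
  invisible(x)
}
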