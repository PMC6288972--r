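#' Construct a gene
#'
#' A gene is a (type, binding sites) pair. There are 16 gene types, numbered
#' 0 to 15: type 0 encodes the morphogen (clamped by the tissue, never
#' transcribed from its own regulatory region) and type 5 the segmentation
#' protein whose final spatial pattern is scored for fitness.
#'
#' @param type integer gene type in 0..15.
#' @param sites binding sites: a two-column integer matrix (columns
#'   `type`, `weight`) or a list of length-2 vectors `c(type, weight)`;
#'   `NULL` for none. Weights are -1 (repressing) or +1 (activating).
#' @return A `cw_gene` list with elements `type` and `sites`.
#' @export
gene <- function(type, sites = NULL) {
  if (is.null(sites)) {
    sites <- matrix(integer(0), ncol = 2)
  } else if (is.list(sites)) {
    sites <- do.call(rbind, lapply(sites, as.integer))
  } else {
    sites <- matrix(as.integer(sites), ncol = 2)
  }
  colnames(sites) <- c("type", "weight")
  g <- structure(list(type = as.integer(type), sites = sites),
                 class = "cw_gene")
  validate_gene(g)
  g
}

validate_gene <- function(g) {
  if (!is.numeric(g$type) || length(g$type) != 1 || g$type < 0 || g$type > 15)
    stop("gene type must be a single integer in 0..15")
  s <- g$sites
  if (!is.matrix(s) || ncol(s) != 2)
    stop("gene sites must be a two-column matrix")
  if (nrow(s) > 0) {
    if (any(s[, 1] < 0 | s[, 1] > 15))
      stop("TFBS bound type must be in 0..15")
    if (any(abs(s[, 2]) != 1))
      stop("TFBS weight must be -1 or +1")
  }
  invisible(g)
}

#' Construct a genome
#'
#' A pearls-on-a-string genome: an ordered list of genes, each with its own
#' upstream binding sites. Duplication and deletion may leave zero or several
#' genes of any type.
#'
#' @param genes list of [gene()] objects.
#' @return A `cw_genome` object.
#' @export
genome <- function(genes = list()) {
  stopifnot(is.list(genes))
  lapply(genes, validate_gene)
  structure(list(genes = genes), class = "cw_genome")
}

#' @export
print.cw_genome <- function(x, ...) {
  cat(sprintf("<cw_genome> %d genes, %d TFBS; types present: %s\n",
              n_genes(x), n_tfbs(x),
              paste(sort(unique(gene_types(x))), collapse = " ")))
  invisible(x)
}

#' Genome element counts
#'
#' @param g a `cw_genome`.
#' @return `n_genes()`: number of genes; `n_tfbs()`: total number of binding
#'   sites; `gene_types()`: integer vector of gene types in genome order.
#' @export
n_genes <- function(g) length(g$genes)

#' @rdname n_genes
#' @export
n_tfbs <- function(g) sum(vapply(g$genes, function(x) nrow(x$sites), 0L))

#' @rdname n_genes
#' @export
gene_types <- function(g) vapply(g$genes, function(x) x$type, 0L)

#' Is a genome viable?
#'
#' Viability requires at least one gene of each of the 16 types; non-viable
#' individuals are not allowed to reproduce (their fitness is 0).
#'
#' @param g a `cw_genome`.
#' @return logical.
#' @export
is_viable <- function(g) length(setdiff(0:15, gene_types(g))) == 0

# Flat integer-vector view used by the C++ core.
flatten_genome <- function(g) {
  types <- gene_types(g)
  ns <- vapply(g$genes, function(x) nrow(x$sites), 0L)
  if (sum(ns) == 0) {
    return(list(gene_types = types, site_gene = integer(0),
                site_type = integer(0), site_weight = integer(0)))
  }
  sites <- do.call(rbind, lapply(g$genes, function(x) x$sites))
  list(gene_types = types,
       site_gene = rep(seq_along(g$genes), ns),
       site_type = as.integer(sites[, 1]),
       site_weight = as.integer(sites[, 2]))
}

#' Random founder genome
#'
#' One gene of each of the 16 types in random order, each carrying a
#' Poisson(`mean_tfbs`) number of binding sites of uniform-random type and
#' uniform-random sign. This is the ancestral genome from which every
#' evolutionary run starts.
#'
#' @param seed optional integer seed (`set.seed`); `NULL` uses the current
#'   RNG state.
#' @param mean_tfbs expected binding sites per gene (>= 0).
#' @return A `cw_genome` with exactly 16 genes, one per type.
#' @export
init_random_genome <- function(seed = NULL, mean_tfbs = 2) {
  stopifnot(mean_tfbs >= 0)
  if (!is.null(seed)) set.seed(seed)
  types <- sample(0:15)
  genes <- lapply(types, function(t) {
    k <- stats::rpois(1, mean_tfbs)
    if (k == 0) return(gene(t))
    gene(t, cbind(sample(0:15, k, replace = TRUE),
                  sample(c(-1L, 1L), k, replace = TRUE)))
  })
  genome(genes)
}

#' Mutate a genome
#'
#' Applies, in a fixed order, the mutational operators acting at
#' reproduction: whole-gene duplication (the copy, with all its sites, is
#' inserted adjacent to the original) and deletion; then per-site weight
#' flips, type randomisation, site duplication and deletion; finally de-novo
#' innovation of one random site per gene. Gene types are never altered.
#' With all rates zero the parent is returned unchanged.
#'
#' @param parent a `cw_genome`.
#' @param rates a [mutation_rates()] object.
#' @param seed optional integer seed for reproducible mutation.
#' @return A new `cw_genome`.
#' @export
mutate_genome <- function(parent, rates = mutation_rates(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- parent$genes
  n0 <- length(genes)
  if (n0 == 0) return(parent)

  # draw all events up front; most reproductions carry no mutation at all,
  # in which case the parent genome is returned as-is
  gdup <- if (rates$gene_dup > 0) stats::runif(n0) < rates$gene_dup
          else logical(n0)
  if (any(gdup)) genes <- genes[rep(seq_len(n0), times = 1L + gdup)]
  n <- length(genes)
  gdel <- if (rates$gene_del > 0) stats::runif(n) < rates$gene_del
          else logical(n)
  if (any(gdel)) genes <- genes[!gdel]
  n <- length(genes)
  if (n == 0) return(structure(list(genes = list()), class = "cw_genome"))

  ns <- vapply(genes, function(g) nrow(g$sites), 0L)
  m <- sum(ns)
  fl <- if (rates$tfbs_weight_change > 0) stats::runif(m) < rates$tfbs_weight_change else logical(m)
  tc <- if (rates$tfbs_type_change > 0) stats::runif(m) < rates$tfbs_type_change else logical(m)
  sdup <- if (rates$tfbs_dup > 0) stats::runif(m) < rates$tfbs_dup else logical(m)
  sdel <- if (rates$tfbs_del > 0) stats::runif(m) < rates$tfbs_del else logical(m)
  inn <- if (rates$tfbs_innovation > 0) stats::runif(n) < rates$tfbs_innovation else logical(n)

  site_events <- any(fl) || any(tc) || any(sdup) || any(sdel) || any(inn)
  if (!any(gdup) && !any(gdel) && !site_events)
    return(parent)
  if (!site_events) # gene-level events only: gene objects are reusable
    return(structure(list(genes = genes), class = "cw_genome"))

  if (m > 0 && (any(fl) || any(tc) || any(sdup) || any(sdel))) {
    S <- do.call(rbind, lapply(genes, function(g) g$sites))
    gi <- rep(seq_len(n), ns)
    S[fl, 2] <- -S[fl, 2]
    if (any(tc)) S[tc, 1] <- sample(0:15, sum(tc), replace = TRUE)
    # dup and del are independent per-site events; deletion removes one
    # copy, so a site hit by both in the same event keeps one copy
    copies <- pmax(1L + sdup - sdel, 0L)
    keep <- rep(seq_len(m), times = copies)
    S <- S[keep, , drop = FALSE]
    gi <- gi[keep]
  } else {
    S <- if (m > 0) do.call(rbind, lapply(genes, function(g) g$sites))
         else matrix(integer(0), ncol = 2)
    gi <- rep(seq_len(n), ns)
  }
  if (any(inn)) {
    k <- sum(inn)
    S <- rbind(S, cbind(sample(0:15, k, replace = TRUE),
                        sample(c(-1L, 1L), k, replace = TRUE)))
    gi <- c(gi, which(inn))
  }

  o <- order(gi) # stable: keeps site order within a gene, innovations last
  S <- S[o, , drop = FALSE]
  gi <- gi[o]
  counts <- tabulate(gi, n)
  ptr <- c(0L, cumsum(counts))
  empty <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("type", "weight")))
  new_genes <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- if (counts[i] > 0) S[(ptr[i] + 1):ptr[i + 1], , drop = FALSE]
            else empty
    colnames(rows) <- c("type", "weight")
    new_genes[[i]] <- structure(list(type = genes[[i]]$type, sites = rows),
                                class = "cw_gene")
  }
  structure(list(genes = new_genes), class = "cw_genome")
}

#' Compile a genome into its signed regulatory network
#'
#' Every binding site upstream of a non-type-0 gene contributes one incoming
#' edge to that gene's type; sites upstream of type-0 genes are inert because
#' the morphogen is clamped by the tissue. Multiple gene copies of one type
#' share a single node (their products form one protein pool), but each
#' copy's incoming edges are kept with the copy's genome index so the
#' network can be mapped back onto the genome.
#'
#' @param g a `cw_genome`.
#' @return A `cw_network`: list with `nodes` (gene types present, plus any
#'   source types referenced by sites) and `edges`
#'   (data.frame `source`, `target`, `weight`, `target_gene_index`).
#' @export
build_network <- function(g) {
  types <- gene_types(g)
  rows <- lapply(seq_along(g$genes), function(i) {
    gn <- g$genes[[i]]
    if (gn$type == 0 || nrow(gn$sites) == 0) return(NULL)
    data.frame(source = as.integer(gn$sites[, 1]),
               target = gn$type,
               weight = as.integer(gn$sites[, 2]),
               target_gene_index = i)
  })
  edges <- do.call(rbind, rows)
  if (is.null(edges))
    edges <- data.frame(source = integer(0), target = integer(0),
                        weight = integer(0), target_gene_index = integer(0))
  structure(list(nodes = sort(unique(c(types, edges$source, edges$target))),
                 edges = edges),
            class = "cw_network")
}

#' @export
print.cw_network <- function(x, ...) {
  cat(sprintf("<cw_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Genome serialization
#'
#' Human-readable text, one record per gene in genome order:
#' `gene <type> : (<site_type>,<+1|-1>) (<site_type>,<+1|-1>) ...`
#' A gene without sites is written as `gene <type> :`. Blank lines and lines
#' starting with `#` are ignored on input; any other malformed record is
#' rejected. Round-trips are lossless.
#'
#' @param g a `cw_genome`.
#' @param path file path.
#' @param lines character vector of serialized records.
#' @return `format_genome()` a character vector (one line per gene);
#'   `parse_genome()`/`read_genome()` a `cw_genome`; `write_genome()` the
#'   genome, invisibly.
#' @export
format_genome <- function(g) {
  vapply(g$genes, function(gn) {
    if (nrow(gn$sites) == 0) return(sprintf("gene %d :", gn$type))
    toks <- sprintf("(%d,%s)", gn$sites[, 1],
                    ifelse(gn$sites[, 2] > 0, "+1", "-1"))
    sprintf("gene %d : %s", gn$type, paste(toks, collapse = " "))
  }, character(1))
}

#' @rdname format_genome
#' @export
parse_genome <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  genes <- lapply(lines, function(ln) {
    m <- regmatches(ln, regexec("^gene\\s+(\\d+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 0)
      stop("malformed genome record: ", ln)
    type <- as.integer(m[2])
    if (type > 15) stop("gene type out of range in record: ", ln)
    rest <- trimws(m[3])
    if (!nzchar(rest)) return(gene(type))
    toks <- strsplit(rest, "\\s+")[[1]]
    sites <- lapply(toks, function(tk) {
      sm <- regmatches(tk, regexec("^\\((\\d+),([+-]1)\\)$", tk))[[1]]
      if (length(sm) == 0)
        stop("malformed TFBS token '", tk, "' in record: ", ln)
      st <- as.integer(sm[2])
      if (st > 15) stop("TFBS type out of range in record: ", ln)
      c(st, as.integer(sm[3]))
    })
    gene(type, sites)
  })
  genome(genes)
}

#' @rdname format_genome
#' @export
write_genome <- function(g, path) {
  writeLines(format_genome(g), path)
  invisible(g)
}

#' @rdname format_genome
#' @export
read_genome <- function(path) parse_genome(readLines(path))
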