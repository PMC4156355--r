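# Transmural strand geometry and fibrosis layout generation.
#
# A StrandLayout is an ordered list of nodes (one node per cell, dx = 0.01 cm
# by default) with a cell class per node and a diffusion coefficient per
# element (the interval between consecutive nodes).  The stimulated
# endocardial end is node 1.  Fibrosis replaces myocyte nodes by fibroblast
# nodes; every element touching a fibroblast node gets its diffusion
# coefficient reduced three-fold relative to the myocyte-myocyte value.

#' Build a 1D transmural strand layout
#'
#' Nodes are ordered endocardium to epicardium (with an optional
#' midmyocardial block for the three-class model); node 1 is the stimulated
#' endocardial end.  All elements start at the myocyte-myocyte diffusion
#' coefficient `D_myo`.
#'
#' @param model_id `"GPB"` (endo/epi) or `"ORd"` (endo/M/epi).
#' @param composition Named vector of node counts, e.g. `c(ENDO = 82, EPI =
#'   83)`; the default is the standard transmural composition for the model:
#'   82 endo + 83 epi (GPB), 60 endo + 45 M + 65 epi (ORd).
#' @param D_myo Myocyte-myocyte diffusion coefficient, cm^2/ms.
#' @param dx Node spacing, cm.
#' @return A `strand_layout`: `n_nodes`, `dx`, `node_class`,
#'   `underlying_class`, `D_elem` (length `n_nodes - 1`), `D_myo`, `seed`,
#'   `provenance`.
#' @examples
#' lay <- build_transmural_layout("GPB")
#' lay$n_nodes                     # 165
#' table(lay$node_class)
#' @export
build_transmural_layout <- function(model_id,
                                    composition = NULL,
                                    D_myo = 0.0006, dx = 0.01) {
  model_id <- match.arg(model_id, c("GPB", "ORd"))
  if (is.null(composition)) {
    composition <- if (model_id == "GPB") c(ENDO = 82, EPI = 83)
                   else c(ENDO = 60, MID = 45, EPI = 65)
  }
  if (is.null(names(composition)) ||
      !all(names(composition) %in% c("ENDO", "MID", "EPI"))) {
    stop("composition must be named with ENDO/MID/EPI", call. = FALSE)
  }
  if (any(composition < 1)) stop("composition counts must be >= 1", call. = FALSE)
  if (model_id == "GPB" && "MID" %in% names(composition)) {
    stop("unsupported model/class pair (GPB, MID): the GPB formulation has ",
         "no M-cell variant", call. = FALSE)
  }
  stopifnot(dx > 0, D_myo > 0)
  order_ <- intersect(c("ENDO", "MID", "EPI"), names(composition))
  node_class <- unlist(lapply(order_, function(cl)
    rep(cl, composition[[cl]])), use.names = FALSE)
  n <- length(node_class)
  if (n < 2) stop("strand needs at least 2 nodes", call. = FALSE)
  structure(list(
    n_nodes = n, dx = dx, model_id = model_id,
    node_class = node_class, underlying_class = node_class,
    D_elem = rep(D_myo, n - 1), D_myo = D_myo, seed = NULL,
    provenance = sprintf("transmural %s strand (%s)", model_id,
                         paste(sprintf("%s:%d", order_, composition[order_]),
                               collapse = " "))),
    class = "strand_layout")
}

# element e joins nodes e and e+1.  Under the default "any" rule an element
# is "fibroblast" (and carries D_myo/3) if either endpoint node is a
# fibroblast; under the "interface" rule only myocyte-fibroblast interface
# elements are reduced and fibroblast-fibroblast elements keep D_myo.
.recompute_D <- function(layout) {
  fib <- layout$node_class == "FIBROBLAST"
  n <- layout$n_nodes
  rule <- if (is.null(layout$d_rule)) "any" else layout$d_rule
  fib_elem <- if (rule == "interface") xor(fib[-n], fib[-1])
              else fib[-n] | fib[-1]
  layout$D_elem <- ifelse(fib_elem, layout$D_myo / 3, layout$D_myo)
  layout
}

#' Choose the fibroblast-element diffusion rule
#'
#' `"any"` (default): every element touching a fibroblast node carries
#' `D_myo/3`.  `"interface"`: only myocyte-fibroblast interface elements are
#' reduced, fibroblast-fibroblast elements keep `D_myo` (used together with
#' capacitance-weighted coupling for the cluster-conduction variant; see the
#' methods vignette).
#'
#' @param layout A `strand_layout`.
#' @param rule `"any"` or `"interface"`.
#' @return The layout with its diffusion map recomputed.
#' @export
fibrosis_d_rule <- function(layout, rule = c("any", "interface")) {
  stopifnot(inherits(layout, "strand_layout"))
  layout$d_rule <- match.arg(rule)
  .recompute_D(layout)
}

#' Insert seeded diffuse fibrosis into a strand
#'
#' Reassigns `round(fraction * n_nodes)` nodes, drawn uniformly without
#' replacement by a seeded generator, to the fibroblast membrane model.
#' Every element touching a fibroblast node gets its diffusion coefficient
#' divided by 3.  The same `(fraction, seed)` pair always produces the same
#' layout.
#'
#' @param layout A `strand_layout`.
#' @param fraction Fibrotic content as a fraction of nodes, in `[0, 0.5]`.
#' @param seed Integer seed for the node draw.
#' @return The modified layout.
#' @export
insert_diffuse_fibrosis <- function(layout, fraction, seed) {
  stopifnot(inherits(layout, "strand_layout"))
  if (!(fraction >= 0 && fraction <= 0.5)) {
    stop("fraction must be in [0, 0.5]", call. = FALSE)
  }
  if (missing(seed) || is.null(seed)) stop("seed must be provided", call. = FALSE)
  # half-up rounding: 10% of 165 nodes -> 17 fibroblasts
  k <- floor(fraction * layout$n_nodes + 0.5)
  if (k == 0) return(layout)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  idx <- sample.int(layout$n_nodes, k)
  layout$node_class[idx] <- "FIBROBLAST"
  layout$seed <- seed
  layout$provenance <- paste0(layout$provenance,
                              sprintf(" + diffuse fibrosis %.0f%% (seed %d)",
                                      100 * fraction, seed))
  .recompute_D(layout)
}

#' Insert a contiguous fibroblast cluster (patchy fibrosis)
#'
#' @param layout A `strand_layout`.
#' @param cluster_size Number of contiguous fibroblast nodes.
#' @param start_index 1-based index of the first node of the cluster.
#' @return The modified layout.
#' @export
insert_patchy_fibrosis <- function(layout, cluster_size = 25, start_index) {
  stopifnot(inherits(layout, "strand_layout"), cluster_size >= 1)
  if (start_index < 1 || start_index + cluster_size - 1 > layout$n_nodes) {
    stop("cluster overflows the strand", call. = FALSE)
  }
  idx <- start_index:(start_index + cluster_size - 1)
  layout$node_class[idx] <- "FIBROBLAST"
  layout$provenance <- paste0(layout$provenance,
                              sprintf(" + patchy cluster %d@%d", cluster_size,
                                      start_index))
  .recompute_D(layout)
}

#' Change the myocyte-myocyte coupling (uncoupling variant)
#'
#' Sets the myocyte-myocyte diffusion coefficient to `D_new`;
#' fibroblast-adjacent elements become `D_new / 3`.
#'
#' @param layout A `strand_layout`.
#' @param D_new New diffusion coefficient, cm^2/ms.
#' @return The modified layout.
#' @export
uncoupling_variant <- function(layout, D_new) {
  stopifnot(inherits(layout, "strand_layout"), D_new > 0)
  layout$D_myo <- D_new
  layout$provenance <- paste0(layout$provenance,
                              sprintf(" + D_myo=%g", D_new))
  .recompute_D(layout)
}

#' Serialize / restore a strand layout as a plain-text node table
#'
#' @param layout A `strand_layout`.
#' @param path File path.
#' @return `write_layout` returns `path` invisibly; `read_layout` returns the
#'   restored `strand_layout`.
#' @export
write_layout <- function(layout, path) {
  hdr <- sprintf("# hfstrand layout | model=%s dx=%g D_myo=%g seed=%s | %s",
                 layout$model_id, layout$dx, layout$D_myo,
                 if (is.null(layout$seed)) "NA" else layout$seed,
                 layout$provenance)
  df <- data.frame(index = seq_len(layout$n_nodes),
                   class = layout$node_class,
                   underlying = layout$underlying_class,
                   D_next = c(layout$D_elem, NA))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(format(df, digits = 17), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec(
    "model=(\\S+) dx=(\\S+) D_myo=(\\S+) seed=(\\S+) \\| (.*)$", hdr))[[1]]
  df <- read.table(path, skip = 1, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, strip.white = TRUE)
  n <- nrow(df)
  structure(list(
    n_nodes = n, dx = as.numeric(m[3]), model_id = m[2],
    node_class = trimws(df$class), underlying_class = trimws(df$underlying),
    D_elem = as.numeric(df$D_next[-n]),
    D_myo = as.numeric(m[4]),
    seed = if (m[5] == "NA") NULL else as.integer(m[5]),
    provenance = m[6]),
    class = "strand_layout")
}
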