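#' Superbasin partition at an energy threshold
#'
#' Minima belong to the same superbasin when they can interconvert by
#' overcoming a barrier less than or equal to the threshold energy: union-find
#' over the transition-state edges with E_ts <= threshold. Labels are
#' deterministic (the smallest member id of each basin).
#'
#' @param db an `elcv_spdb`.
#' @param threshold threshold energy.
#' @return integer vector of basin labels, one per minimum.
#' @export
superbasin_partition <- function(db, threshold) {
  if (n_minima(db) < 1) stop("empty database", call. = FALSE)
  keep <- which(db$ts$energy <= threshold)
  edges <- if (length(keep)) cbind(db$ts$min1[keep], db$ts$min2[keep]) else
    matrix(integer(0), ncol = 2)
  uf_components(n_minima(db), edges)
}

#' Build a disconnectivity tree
#'
#' Superbasin partitions are computed at descending thresholds `e_top`,
#' `e_top - delta_e`, ...; an internal node is created at the lowest threshold
#' at which a basin is still merged (the level just above where it splits),
#' and every minimum terminates as a leaf at its own energy.
#'
#' @param db an `elcv_spdb`.
#' @param delta_e uniform level spacing (> 0); defaults to
#'   (e_top - global minimum)/50.
#' @param e_top top threshold; must lie above the global minimum and should be
#'   above the highest transition state for a complete tree.
#' @return an `elcv_disc_tree`: recursive node structure plus bookkeeping.
#' @export
build_tree <- function(db, delta_e = NULL, e_top = NULL) {
  e_gm <- min(db$minima$energy)
  if (is.null(e_top)) {
    e_top <- if (nrow(db$ts)) max(db$ts$energy) + 1e-9 else
      max(db$minima$energy) + 1e-9
    e_top <- max(e_top, e_gm + 1e-6)
  }
  if (e_top < e_gm)
    stop("e_top lies below the global minimum", call. = FALSE)
  if (is.null(delta_e)) delta_e <- max((e_top - e_gm) / 50, 1e-12)
  if (!(delta_e > 0)) stop("delta_e must be positive", call. = FALSE)
  n_levels <- ceiling((e_top - e_gm) / delta_e) + 2L
  thresholds <- e_top - (seq_len(n_levels) - 1L) * delta_e

  part_at <- function(t) superbasin_partition(db, t)

  build <- function(ids, level) {
    if (length(ids) == 1L) {
      return(list(type = "leaf", min_id = ids,
                  energy = db$minima$energy[ids]))
    }
    if (level >= n_levels) {
      # below every threshold; should not happen for a valid database, but
      # guard by splitting into leaves
      return(list(type = "node", energy = thresholds[n_levels],
                  children = lapply(ids, function(i)
                    list(type = "leaf", min_id = i,
                         energy = db$minima$energy[i]))))
    }
    labs <- part_at(thresholds[level + 1L])[ids]
    groups <- split(ids, labs)
    if (length(groups) == 1L) return(build(ids, level + 1L))
    list(type = "node", energy = thresholds[level],
         children = lapply(unname(groups), build, level = level + 1L))
  }

  top_labs <- part_at(thresholds[1])
  groups <- split(seq_len(n_minima(db)), top_labs)
  root <- if (length(groups) == 1L) {
    build(seq_len(n_minima(db)), 1L)
  } else {
    list(type = "node", energy = thresholds[1],
         children = lapply(unname(groups), build, level = 1L))
  }
  structure(list(root = root, delta_e = delta_e, e_top = e_top,
                 n_minima = n_minima(db), leaf_colours = NULL),
            class = "elcv_disc_tree")
}

tree_walk_leaves <- function(node, fn) {
  if (node$type == "leaf") return(list(fn(node)))
  do.call(c, lapply(node$children, tree_walk_leaves, fn = fn))
}

#' Leaves of a disconnectivity tree
#' @param tree an `elcv_disc_tree`.
#' @return data frame with `min_id` and `energy`, in tree order.
#' @export
tree_leaves <- function(tree) {
  rows <- tree_walk_leaves(tree$root, function(l)
    data.frame(min_id = l$min_id, energy = l$energy))
  do.call(rbind, rows)
}

#' @export
print.elcv_disc_tree <- function(x, ...) {
  cat(sprintf("<disconnectivity tree: %d leaves, levels every %.4g below %.6g%s>\n",
              x$n_minima, x$delta_e, x$e_top,
              if (!is.null(x$leaf_colours)) ", coloured" else ""))
  invisible(x)
}

#' Colour tree leaves by feature contribution sets
#'
#' Each leaf is labelled by the first matching (feature, sign) class: feature
#' 1's positive/negative sets take the first two palette labels, feature 2's
#' the next two, and so on (earlier features win overlaps). Unmatched leaves
#' are labelled "neutral".
#'
#' @param tree an `elcv_disc_tree`.
#' @param features list of features augmented by [feature_contributions()].
#' @param palette character labels, two per feature (positive first).
#' @return the tree with a `leaf_colours` named vector (by minimum id).
#' @export
colour_leaves <- function(tree, features,
                          palette = c("red", "blue", "green", "orange",
                                      "pink", "purple", "grey", "yellow")) {
  cols <- rep("neutral", tree$n_minima)
  names(cols) <- as.character(seq_len(tree$n_minima))
  for (k in rev(seq_along(features))) {
    f <- features[[k]]
    ids <- c(f$positive_set$id, f$negative_set$id)
    if (any(ids < 1 | ids > tree$n_minima))
      stop("contribution set references unknown minimum id", call. = FALSE)
    ppos <- palette[min(2 * k - 1, length(palette))]
    pneg <- palette[min(2 * k, length(palette))]
    cols[as.character(f$positive_set$id)] <- ppos
    cols[as.character(f$negative_set$id)] <- pneg
  }
  tree$leaf_colours <- cols
  tree
}

tree_to_plain <- function(node) {
  if (node$type == "leaf") {
    list(type = "leaf", min_id = node$min_id, energy = node$energy)
  } else {
    list(type = "node", energy = node$energy,
         children = lapply(node$children, tree_to_plain))
  }
}

#' Serialize a disconnectivity tree to JSON
#' @param tree an `elcv_disc_tree`.
#' @param path output file.
#' @export
write_tree_json <- function(tree, path) {
  obj <- list(e_top = tree$e_top, delta_e = tree$delta_e,
              n_minima = tree$n_minima, root = tree_to_plain(tree$root),
              leaf_colours = as.list(tree$leaf_colours))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_atomic(json, path)
}

tree_subtree_size <- function(node) {
  if (node$type == "leaf") return(1L)
  sum(vapply(node$children, tree_subtree_size, integer(1)))
}

#' Plot a disconnectivity tree
#'
#' Base-graphics rendering: leaves are ordered by recursive subtree size,
#' branches drop vertically from each node to its children, and leaf branches
#' terminate at the energy of the corresponding minimum. Leaf colours follow
#' [colour_leaves()] when present.
#'
#' @param x an `elcv_disc_tree`.
#' @param y ignored.
#' @param ... passed to [graphics::plot()].
#' @export
plot.elcv_disc_tree <- function(x, y, ...) {
  counter <- new.env()
  counter$next_x <- 1
  layout_node <- function(node) {
    if (node$type == "leaf") {
      xp <- counter$next_x
      counter$next_x <- counter$next_x + 1
      node$x <- xp
      return(node)
    }
    sizes <- vapply(node$children, tree_subtree_size, integer(1))
    node$children <- lapply(node$children[order(-sizes)], layout_node)
    node$x <- mean(vapply(node$children, `[[`, numeric(1), "x"))
    node
  }
  root <- layout_node(x$root)
  emin <- min(tree_leaves(x)$energy)
  graphics::plot(NA, xlim = c(0.5, x$n_minima + 0.5),
                 ylim = c(emin, x$e_top), xaxt = "n", xlab = "",
                 ylab = "energy", ...)
  cols <- x$leaf_colours
  pal <- c(neutral = "black", red = "red", blue = "blue", green = "green3",
           orange = "orange", pink = "hotpink", purple = "purple",
           grey = "grey50", yellow = "gold")
  draw <- function(node) {
    if (node$type == "leaf") return(invisible())
    for (ch in node$children) {
      col <- "black"
      if (ch$type == "leaf" && !is.null(cols)) {
        lab <- cols[as.character(ch$min_id)]
        if (!is.na(lab) && lab %in% names(pal)) col <- pal[[lab]]
      }
      graphics::segments(ch$x, node$energy, ch$x, ch$energy, col = col)
      graphics::segments(node$x, node$energy, ch$x, node$energy, col = "grey40")
      draw(ch)
    }
  }
  draw(root)
  invisible(x)
}
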