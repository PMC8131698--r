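# Clone ordering from single-colony genotype matrices under the
# infinite-sites assumption: each mutation is acquired once and never lost,
# so the colony set of a later mutation must be contained in that of an
# earlier one. Containment violations are reported, never silently resolved.

#' Infer clonal acquisition order from a colony genotype matrix
#'
#' Builds the containment partial order over mutations: A is ancestral to B
#' when the colonies carrying B are a subset of those carrying A, allowing a
#' fraction of at most `tolerance` of B's colonies to violate the containment
#' (to accommodate Sanger dropout). Mutations whose colony sets are mutually
#' contained (identical at tolerance 0) are merged into a single acquisition
#' step, since their order is unidentifiable; mutations with incomparable,
#' overlapping colony sets are reported as conflicts, and incomparable
#' disjoint sets become sibling branches. Each colony is then assigned to the
#' clone whose genotype it matches best (ties toward the ancestral side) and
#' per-clone prevalences are computed.
#'
#' @param genotypes binary colonies x mutations matrix with unique row and
#'   column names.
#' @param tolerance allowed violating fraction per containment check
#'   (default 0 = strict).
#' @return list of class `clone_trajectory`: `clones` (list of mutation
#'   character vectors, ancestral first), `table` (clone, parent, mutations,
#'   count, prevalence), `conflicts` (data.frame of violating pairs with
#'   their violation fractions), `linear` (TRUE when the trajectory is a
#'   single path).
#' @export
infer_clone_order <- function(genotypes, tolerance = 0) {
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) < 1) stop("need at least one colony", call. = FALSE)
  if (!all(genotypes %in% c(0, 1))) {
    stop("genotype matrix must be strictly binary", call. = FALSE)
  }
  if (is.null(colnames(genotypes))) {
    colnames(genotypes) <- paste0("m", seq_len(ncol(genotypes)))
  }
  if (is.null(rownames(genotypes))) {
    rownames(genotypes) <- paste0("colony", seq_len(nrow(genotypes)))
  }
  if (anyDuplicated(rownames(genotypes)) || anyDuplicated(colnames(genotypes))) {
    stop("duplicate row or column identifiers", call. = FALSE)
  }
  check_prob(tolerance, "tolerance")
  n_col <- nrow(genotypes)
  muts <- colnames(genotypes)

  # fraction of B's colonies not carried by A (0 when B subset of A)
  viol <- function(a, b) {
    nb <- sum(genotypes[, b])
    if (nb == 0) return(0)
    sum(genotypes[, b] == 1 & genotypes[, a] == 0) / nb
  }

  # merge mutations with mutually contained colony sets into one step
  groups <- list()
  assigned <- rep(NA_integer_, length(muts))
  for (i in seq_along(muts)) {
    if (!is.na(assigned[i])) next
    grp <- i
    for (j in seq_along(muts)) {
      if (j == i || !is.na(assigned[j])) next
      if (viol(muts[i], muts[j]) <= tolerance &&
          viol(muts[j], muts[i]) <= tolerance) grp <- c(grp, j)
    }
    assigned[grp] <- length(groups) + 1L
    groups[[length(groups) + 1L]] <- muts[grp]
  }
  g_count <- vapply(groups, function(g)
    max(colSums(genotypes[, g, drop = FALSE])), numeric(1))

  # mutations never observed in any colony carry no ordering information
  observed <- g_count > 0
  groups <- groups[observed]
  g_count <- g_count[observed]

  # containment relations between merged groups and conflicts
  ng <- length(groups)
  contains <- matrix(FALSE, ng, ng)   # [a, b]: a ancestral to (contains) b
  conflicts <- list()
  if (ng > 1) {
    for (a in seq_len(ng)) {
      for (b in seq_len(ng)) {
        if (a == b) next
        v <- max(vapply(groups[[a]], function(ma)
          max(vapply(groups[[b]], function(mb) viol(ma, mb), numeric(1))),
          numeric(1)))
        contains[a, b] <- v <= tolerance
      }
    }
    for (a in seq_len(ng - 1)) {
      for (b in (a + 1):ng) {
        if (contains[a, b] || contains[b, a]) next
        overlap <- sum(rowSums(genotypes[, groups[[a]], drop = FALSE]) > 0 &
                       rowSums(genotypes[, groups[[b]], drop = FALSE]) > 0)
        if (overlap > 0) {
          conflicts[[length(conflicts) + 1L]] <- data.frame(
            group_a = paste(groups[[a]], collapse = "+"),
            group_b = paste(groups[[b]], collapse = "+"),
            violation = min(viol(groups[[a]][1], groups[[b]][1]),
                            viol(groups[[b]][1], groups[[a]][1])),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  conflicts <- if (length(conflicts)) do.call(rbind, conflicts) else
    data.frame(group_a = character(), group_b = character(),
               violation = numeric(), stringsAsFactors = FALSE)

  # parent of each group: the containing group with the smallest colony count
  ord <- order(-g_count)
  parent <- rep(0L, ng)               # 0 = ancestral (wild-type) clone
  for (b in seq_len(ng)) {
    anc <- which(contains[, b] & seq_len(ng) != b)
    if (length(anc)) parent[b] <- anc[which.min(g_count[anc])]
  }

  # clone genotypes: mutations along the path from the root
  clone_muts <- vector("list", ng)
  path_muts <- function(g) {
    out <- character()
    steps <- 0L
    while (g != 0L) {
      out <- c(groups[[g]], out)
      g <- parent[g]
      steps <- steps + 1L
      if (steps > ng) {  # containment cycle possible only at tolerance > 0
        stop("cyclic containment at this tolerance; lower `tolerance`",
             call. = FALSE)
      }
    }
    out
  }
  for (g in seq_len(ng)) clone_muts[[g]] <- path_muts(g)

  # order clones root-to-leaf: by depth, then by descending colony count
  depth <- vapply(clone_muts, length, numeric(1))
  clone_order <- ord[order(depth[ord])]
  clones <- c(list(character(0)), clone_muts[clone_order])
  parent_idx <- c(NA_integer_,
                  vapply(clone_order, function(g) {
                    if (parent[g] == 0L) 1L
                    else which(clone_order == parent[g]) + 1L
                  }, integer(1)))

  # assign each colony to the best-matching clone genotype
  clone_vec <- vapply(clones, function(cm) as.numeric(muts %in% cm),
                      numeric(length(muts)))
  clone_vec <- matrix(clone_vec, nrow = length(muts))
  agree <- genotypes %*% clone_vec + (1 - genotypes) %*% (1 - clone_vec)
  assign_clone <- apply(agree, 1, which.max)   # ties -> earlier (ancestral)
  counts <- tabulate(assign_clone, nbins = length(clones))

  tab <- data.frame(
    clone = seq_along(clones),
    parent = parent_idx,
    mutations = vapply(clones, function(cm)
      if (length(cm)) paste(cm, collapse = "+") else "WT", character(1)),
    n_mutations = vapply(clones, length, integer(1)),
    count = counts,
    prevalence = counts / n_col,
    stringsAsFactors = FALSE
  )
  n_children <- tabulate(parent_idx[-1], nbins = length(clones))
  structure(list(clones = clones, table = tab, conflicts = conflicts,
                 linear = all(n_children <= 1), n_colonies = n_col),
            class = "clone_trajectory")
}

#' @export
print.clone_trajectory <- function(x, ...) {
  cat(sprintf("clone trajectory over %d colonies (%s)%s\n", x$n_colonies,
              if (x$linear) "linear" else "branching",
              if (nrow(x$conflicts)) sprintf(", %d conflicts", nrow(x$conflicts))
              else ""))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Fishplot-ready clone prevalence table
#'
#' @param trajectory a `clone_trajectory` from [infer_clone_order()].
#' @return data.frame ordered root-to-leaf (clone, parent, mutations, count,
#'   prevalence); prevalences sum to 1.
#' @export
fishplot_table <- function(trajectory) {
  if (!inherits(trajectory, "clone_trajectory") ||
      is.null(trajectory$table) || nrow(trajectory$table) == 0) {
    stop("not a valid clone trajectory", call. = FALSE)
  }
  trajectory$table
}
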