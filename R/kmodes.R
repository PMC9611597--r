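#' Empowerment item set
#'
#' The ten nominal survey items used throughout the package: five
#' wife-beating-justification attitude items (\code{v_*}), four household
#' decision-making items (\code{d_*}), and one justification-to-refuse-sex
#' item.  The declared level order is also the deterministic tie-break order
#' for mode updates.
#'
#' @return Named list of character vectors: admissible levels per item.
#' @export
empowerment_items <- function() {
  v <- c("yes", "no", "dont_know")
  d <- c("self", "with_partner", "partner", "other")
  list(
    v_burns = v, v_refuse = v, v_argue = v, v_neglect = v, v_goout = v,
    d_visit = d, d_purchase = d, d_health = d,
    d_spend = c(d, "no_earnings"),
    refuse_sex = v)
}

item_names <- function() names(empowerment_items())

#' Validate a table of response vectors
#'
#' Enforces the complete-case contract: every item column present, every
#' entry one of the admissible levels, no missing values.
#'
#' @param x data.frame containing the ten item columns (extra columns are
#'   ignored).
#' @return \code{x[, item columns]} as character columns, invisibly checked.
#' @export
validate_responses <- function(x) {
  lv <- empowerment_items()
  miss <- setdiff(names(lv), names(x))
  if (length(miss)) stop("missing item columns: ", paste(miss, collapse = ", "))
  out <- x[names(lv)]
  for (it in names(lv)) {
    col <- as.character(out[[it]])
    if (anyNA(col)) stop("missing values in item ", it, " (complete cases required)")
    bad <- !(col %in% lv[[it]])
    if (any(bad))
      stop("inadmissible level '", col[which(bad)[1]], "' in item ", it,
           " (row ", which(bad)[1], ")")
    out[[it]] <- col
  }
  out
}

make_mode <- function(violence, decisions, refuse, spend = decisions) {
  data.frame(v_burns = violence, v_refuse = violence, v_argue = violence,
             v_neglect = violence, v_goout = violence,
             d_visit = decisions, d_purchase = decisions, d_health = decisions,
             d_spend = spend, refuse_sex = refuse,
             stringsAsFactors = FALSE)
}

#' Conceptually primed initial modes
#'
#' The five initial cluster modes used to prime the k-modes algorithm:
#' 1 "more empowered" (rejects all violence justifications, decides jointly
#' with partner, may refuse sex), 2 "less empowered" (the opposite),
#' 3 "modal empowered" (rejects violence, partner decides, may refuse sex),
#' 4 "autonomous" (as 1 but decides alone), 5 "other" (all neutral
#' responses).
#'
#' @return data.frame with 5 rows and the ten item columns.
#' @export
default_initial_modes <- function() {
  rbind(
    make_mode("no",        "with_partner", "yes"),
    make_mode("yes",       "partner",      "no"),
    make_mode("no",        "partner",      "yes"),
    make_mode("no",        "self",         "yes"),
    make_mode("dont_know", "other",        "dont_know"))
}

#' Category response templates (resulting modes)
#'
#' The converged modes that the primed k-modes run settles on: categories
#' 1-3 keep their initial modes; category 4 keeps "self" for visit, purchase
#' and health decisions but "partner" for spending; category 5 becomes
#' violence "dont_know", decisions "partner", refuse-sex "no".  These serve
#' as the generating templates of the synthetic-data module.
#'
#' @return data.frame with 5 rows and the ten item columns.
#' @export
default_templates <- function() {
  rbind(
    make_mode("no",        "with_partner", "yes"),
    make_mode("yes",       "partner",      "no"),
    make_mode("no",        "partner",      "yes"),
    make_mode("no",        "self",         "yes", spend = "partner"),
    make_mode("dont_know", "partner",      "no"))
}

#' Simple matching distance between response vectors
#'
#' Counts the items on which two complete response vectors disagree
#' (0 to 10).
#'
#' @param a,b single response vectors: named character vectors, single-row
#'   data.frames, or lists with the ten item entries.
#' @return nonnegative integer.
#' @export
matching_distance <- function(a, b) {
  its <- item_names()
  a <- unlist(a[its]); b <- unlist(b[its])
  sum(as.character(a) != as.character(b))
}

# n x k matrix of matching distances from each row of `data` to each mode
distance_to_modes <- function(data, modes) {
  its <- item_names()
  n <- nrow(data); k <- nrow(modes)
  D <- matrix(0L, n, k)
  for (it in its) {
    col <- data[[it]]
    for (m in seq_len(k)) D[, m] <- D[, m] + (col != modes[[it]][m])
  }
  D
}

#' Item-wise plurality mode of a set of response vectors
#'
#' Returns the per-item most frequent level among the members; ties are
#' broken toward the lowest level in the declared level order of
#' \code{\link{empowerment_items}}.
#'
#' @param members data.frame of response vectors (>= 1 row).
#' @return single-row data.frame.
#' @export
update_mode <- function(members) {
  if (NROW(members) == 0L) stop("empty cluster: cannot form a mode")
  lv <- empowerment_items()
  out <- lapply(names(lv), function(it) {
    counts <- tabulate(match(members[[it]], lv[[it]]), nbins = length(lv[[it]]))
    lv[[it]][which.max(counts)]   # which.max takes the first max: lowest level order
  })
  names(out) <- names(lv)
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' k-modes clustering of nominal response vectors
#'
#' Batch (Lloyd-style) k-modes: alternately assign every respondent to the
#' nearest mode under the simple matching distance and replace each mode by
#' the item-wise plurality of its members, until the labels stop changing or
#' \code{max_iter} is reached.  Assignment ties go to the lowest mode index;
#' an emptied cluster is re-seeded with the observation farthest from its
#' currently assigned mode.  The total matching cost is non-increasing
#' across iterations.
#'
#' @param data data.frame holding the ten item columns (extra columns
#'   ignored); complete cases required.
#' @param modes initial modes, default \code{\link{default_initial_modes}};
#'   must be pairwise distinct.
#' @param max_iter maximum number of assign/update sweeps.
#' @return Object of class \code{kmodes}: \code{cluster} (integer labels),
#'   \code{modes} (final modes), \code{cost} (sum of matching distances to
#'   assigned modes), \code{cost_history}, \code{sizes}, \code{iterations},
#'   \code{converged}.
#' @examples
#' tpl <- default_templates()[1:3, ]
#' x <- tpl[rep(1:3, each = 20), ]
#' fit <- kmodes(x, modes = default_initial_modes()[1:3, ])
#' table(fit$cluster)
#' @export
kmodes <- function(data, modes = default_initial_modes(), max_iter = 100L) {
  data <- validate_responses(data)
  modes <- validate_responses(modes)
  k <- nrow(modes)
  if (k < 1L) stop("need at least one mode")
  D0 <- distance_to_modes(modes, modes)
  if (any(D0[upper.tri(D0)] == 0L)) stop("initial modes must be pairwise distinct")
  n <- nrow(data)
  if (n == 0L) stop("no data to cluster")

  assign_step <- function(modes) {
    D <- distance_to_modes(data, modes)
    lab <- max.col(-D, ties.method = "first")   # ties -> lowest mode index
    list(labels = lab, cost = sum(D[cbind(seq_len(n), lab)]), D = D)
  }

  a <- assign_step(modes)
  labels <- a$labels
  cost_history <- a$cost
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    new_modes <- modes
    for (m in seq_len(k)) {
      idx <- which(labels == m)
      if (length(idx)) {
        new_modes[m, ] <- update_mode(data[idx, , drop = FALSE])
      } else {
        # re-seed with the observation farthest from its current mode; ties
        # broken by item-vector order so the result is row-order invariant
        dcur <- a$D[cbind(seq_len(n), labels)]
        cand <- which(dcur == max(dcur))
        key <- do.call(paste, c(data[cand, , drop = FALSE], sep = "\r"))
        new_modes[m, ] <- data[cand[order(key)[1L]], ]
      }
    }
    a <- assign_step(new_modes)
    cost_history <- c(cost_history, a$cost)
    no_change <- identical(a$labels, labels) &&
      all(unlist(new_modes, use.names = FALSE) == unlist(modes, use.names = FALSE))
    modes <- new_modes
    labels <- a$labels
    if (no_change) { converged <- TRUE; break }
  }
  rownames(modes) <- NULL
  structure(
    list(cluster = labels, modes = modes, cost = a$cost,
         cost_history = cost_history,
         sizes = tabulate(labels, nbins = k),
         iterations = iter, converged = converged),
    class = "kmodes")
}

#' @export
print.kmodes <- function(x, ...) {
  cat("k-modes clustering:", nrow(x$modes), "modes,",
      length(x$cluster), "observations\n")
  cat("cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat("matching cost:", x$cost,
      if (x$converged) sprintf("(converged in %d iterations)", x$iterations)
      else sprintf("(max_iter = %d reached without convergence)", x$iterations), "\n")
  invisible(x)
}
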