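## Nearest-neighbor contact-category probabilities from cell-type maps.
## Contacts are unordered pairs partitioned into four categories: beta-beta
## homotypic, beta heterotypic (beta with alpha or delta), alpha/delta
## homotypic (alpha-alpha or delta-delta), and alpha-delta heterotypic.
## Probabilities are each category's share of all contacts, so the four
## sum to 1 on fully typed maps.

#' Cell-type contact probabilities of an islet
#'
#' @param arch an \code{architecture_map} (see
#'   \code{\link{generate_architecture}}), or any list with a \code{cells}
#'   data.frame (cell_id, type in beta/alpha/delta) and a \code{contacts}
#'   data.frame of unordered cell-index pairs (i, j). Duplicate and
#'   self-contacts are removed before counting.
#' @return An object of class \code{contact_probabilities}: list with
#'   \code{counts} and \code{probabilities}, each over categories
#'   \code{beta_homotypic}, \code{beta_heterotypic},
#'   \code{alpha_delta_homotypic}, \code{alpha_delta_heterotypic}, plus
#'   \code{n_contacts}.
#' @export
contact_probabilities <- function(arch) {
  cells <- arch$cells
  contacts <- arch$contacts
  if (is.null(cells) || is.null(contacts)) stop_input("need cells and contacts")
  if (nrow(contacts) == 0L) stop_input("empty contact graph")
  if (any(is.na(cells$type)) || !all(cells$type %in% c("beta", "alpha", "delta")))
    stop_input("every cell must be typed beta/alpha/delta")
  i <- pmin(contacts$i, contacts$j)
  j <- pmax(contacts$i, contacts$j)
  keep <- i != j & !duplicated(paste(i, j))
  i <- i[keep]; j <- j[keep]
  if (any(i < 1L | j > nrow(cells)))
    stop_input("contact references a cell id outside the cell table")
  ti <- cells$type[i]; tj <- cells$type[j]
  cat4 <- ifelse(ti == "beta" & tj == "beta", "beta_homotypic",
          ifelse(ti == "beta" | tj == "beta", "beta_heterotypic",
          ifelse(ti == tj, "alpha_delta_homotypic", "alpha_delta_heterotypic")))
  lv <- c("beta_homotypic", "beta_heterotypic",
          "alpha_delta_homotypic", "alpha_delta_heterotypic")
  counts <- table(factor(cat4, levels = lv))
  structure(list(counts = as.integer(counts),
                 probabilities = stats::setNames(as.numeric(counts) / length(cat4), lv),
                 n_contacts = length(cat4)),
            class = "contact_probabilities")
}

#' @export
print.contact_probabilities <- function(x, ...) {
  cat("contact_probabilities over", x$n_contacts, "contacts:\n")
  print(round(x$probabilities, 3))
  invisible(x)
}

#' Compare contact probabilities between two groups of mice
#'
#' Islets are technical replicates: per-islet probabilities are averaged
#' per mouse and the per-mouse means are the biological replicates entering
#' the group comparison (dispatched to the statistical decision tree).
#'
#' @param group_a,group_b lists of \code{contact_probabilities}, one per
#'   islet.
#' @param mice_a,mice_b mouse identifier for each islet (same length as
#'   the corresponding group); at least 2 distinct mice per group.
#' @param categories categories to compare (default all four).
#' @return data.frame with one row per category: per-group per-mouse means
#'   (as list columns \code{mouse_means_a/b}), group means, the test used
#'   and its p-value.
#' @export
compare_architectures <- function(group_a, group_b, mice_a, mice_b,
                                  categories = c("beta_homotypic",
                                                 "beta_heterotypic",
                                                 "alpha_delta_homotypic",
                                                 "alpha_delta_heterotypic")) {
  if (length(mice_a) != length(group_a) || length(mice_b) != length(group_b))
    stop_input("every islet must be mapped to a mouse")
  if (any(is.na(mice_a)) || any(is.na(mice_b)))
    stop_input("unmapped islet (NA mouse id)")
  if (length(unique(mice_a)) < 2L || length(unique(mice_b)) < 2L)
    stop_input("need at least 2 mice per group")
  per_mouse <- function(group, mice, cat) {
    v <- vapply(group, function(p) p$probabilities[[cat]], numeric(1))
    as.numeric(tapply(v, mice, mean))
  }
  out <- lapply(categories, function(cat) {
    a <- per_mouse(group_a, mice_a, cat)
    b <- per_mouse(group_b, mice_b, cat)
    rep_ <- choose_and_run(a, b)
    data.frame(category = cat, mean_a = mean(a), mean_b = mean(b),
               test_used = rep_$test_used, p_value = rep_$p_value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
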