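# Geometric value profile: k positive integers decaying by ratio r whose sum
# is exactly `total` (the first entry absorbs the rounding remainder).
tail_profile <- function(total, k, r = 0.75) {
  if (k == 0L || total <= 0) return(integer(0))
  w <- r^(0:(k - 1L))
  v <- round(total * w / sum(w))
  v[v < 1] <- 1L
  v[1L] <- v[1L] + (total - sum(v))
  sort(as.integer(v), decreasing = TRUE)
}

#' Generate a synthetic engager feature table
#'
#' Emulates the three engager roles of the observed COVID-19 microblogging
#' sample as density-separated groups whose generated per-feature means match
#' the published role profile (see [role_feature_means()]):
#'
#' * **advocates** draw all features stochastically: original messages from an
#'   over-dispersed negative binomial centred on 34.571, mentions/topics/links
#'   from near-Poisson negative binomials centred on 0.305/1.022/1.079, and
#'   Poisson(3) shares;
#' * **supporters** draw original messages (negative binomial, mean 1.733) and
#'   Poisson(2) shares stochastically, while the mass of the rare features
#'   (mentions 0.193, topics 0.482, links 0.497) is carried by a fixed 2%
#'   quota of "power users" with a deterministic geometric value profile that
#'   sums to `round(mean * n)` — most users never use those features while a
#'   few use them heavily, and the group means are exact by construction;
#' * **amplifiers** have structural zeros in all original-activity features
#'   and heavy Poisson(400) share counts (sharing is their only activity).
#'
#' The output row order is randomized and the table is reproducible given
#' `seed`.
#'
#' @param n_advocates,n_supporters,n_amplifiers group sizes (the observed
#'   sample scaled by 1/100 gives the default fixture 104/656/1182).
#' @param seed integer seed.
#' @return Data frame with columns `user_id, n_original, n_mentions,
#'   n_topics, n_links, n_shares` and a ground-truth `group` column naming
#'   the generating role.
#' @export
generate_synthetic_engagers <- function(n_advocates = 104,
                                        n_supporters = 656,
                                        n_amplifiers = 1182,
                                        seed = 1) {
  stopifnot(n_advocates >= 0, n_supporters >= 0, n_amplifiers >= 0)
  set.seed(seed)
  prof <- role_feature_means()
  adv_mu <- prof[prof$role == "advocate", ]
  sup_mu <- prof[prof$role == "supporter", ]
  rnb <- function(n, mu, size) {
    if (n == 0L) return(integer(0))
    stats::rnbinom(n, mu = mu, size = size)
  }
  adv <- data.frame(
    n_original = rnb(n_advocates, adv_mu$n_original, 500),
    n_mentions = rnb(n_advocates, adv_mu$n_mentions, 100),
    n_topics = rnb(n_advocates, adv_mu$n_topics, 100),
    n_links = rnb(n_advocates, adv_mu$n_links, 100),
    n_shares = if (n_advocates) stats::rpois(n_advocates, 3) else integer(0))
  quota <- if (n_supporters > 0) max(1L, round(0.02 * n_supporters)) else 0L
  rare <- function(mu) {
    x <- integer(n_supporters)
    if (quota > 0L)
      x[seq_len(quota)] <- tail_profile(round(mu * n_supporters), quota)
    x
  }
  sup <- data.frame(
    n_original = rnb(n_supporters, sup_mu$n_original, 30),
    n_mentions = rare(sup_mu$n_mentions),
    n_topics = rare(sup_mu$n_topics),
    n_links = rare(sup_mu$n_links),
    n_shares = if (n_supporters) stats::rpois(n_supporters, 2) else integer(0))
  amp <- data.frame(
    n_original = integer(n_amplifiers),
    n_mentions = integer(n_amplifiers),
    n_topics = integer(n_amplifiers),
    n_links = integer(n_amplifiers),
    n_shares = if (n_amplifiers) stats::rpois(n_amplifiers, 400) else integer(0))
  out <- rbind(adv, sup, amp)
  out$group <- rep(c("advocate", "supporter", "amplifier"),
                   c(n_advocates, n_supporters, n_amplifiers))
  n <- nrow(out)
  if (n > 1L) out <- out[sample.int(n), ]
  out <- cbind(user_id = sprintf("u%05d", seq_len(n)), out)
  rownames(out) <- NULL
  out
}

check_engager_table <- function(table) {
  if (!is.data.frame(table))
    validation_error("engager table must be a data frame")
  missing <- setdiff(c("user_id", ENGAGER_FEATURES), names(table))
  if (length(missing))
    validation_error(paste("engager table lacks column(s):",
                           paste(missing, collapse = ", ")))
  if (anyDuplicated(table$user_id))
    validation_error("user_id values must be unique")
  for (f in ENGAGER_FEATURES) {
    if (!is.numeric(table[[f]]) || any(table[[f]] < 0, na.rm = TRUE) ||
        anyNA(table[[f]]))
      validation_error(sprintf("feature '%s' must be non-negative and complete", f))
  }
  invisible(table)
}

#' Read / write an engager feature table
#'
#' Delimited text with a header row
#' `user_id,n_original,n_mentions,n_topics,n_links,n_shares`.
#'
#' @param path file path.
#' @return `read_engager_table()`: the validated data frame.
#' @export
read_engager_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) validation_error(paste("empty engager table:", path))
  check_engager_table(tab)
}

#' @param table an engager feature table.
#' @rdname read_engager_table
#' @export
write_engager_table <- function(table, path) {
  check_engager_table(table)
  utils::write.csv(table[, c("user_id", ENGAGER_FEATURES)], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
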