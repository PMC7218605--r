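# shared fixtures, memoized across test files within a run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) assign(name, fn(), envir = .fixtures)
  .fixtures[[name]]
}

test_vocab <- function() {
  fixture("vocab", function() make_synthetic_vocabulary(20, 10, seed = 7))
}

test_cause_model <- function() {
  fixture("cause_model", function() make_cause_model(test_vocab(), seed = 3))
}

tiny_config <- function(vocab, ...) {
  model_config(vocab, embed_dim = 12L, conv_channels = c(12L, 16L),
               seed = 42L, ...)
}

# a cheap trained coder for behavioural tests (not the accuracy runs)
tiny_trained_coder <- function() {
  fixture("tiny_coder", function() {
    v <- test_vocab()
    m <- test_cause_model()
    train <- generate_dataset(m, 600, seed = 21)
    val <- generate_dataset(m, 120, seed = 22)
    coder <- build_model(tiny_config(v), v)
    train_coder(coder, train, val, v,
                opt_params = list(epochs = 3, batch_size = 128, seed = 5),
                quiet = TRUE)
  })
}

# --- independent brute-force oracle -----------------------------------------
# Re-implements the coding rules by naive enumeration, with reachability
# delegated to igraph; shares no code with oracle_code().

bf_graph <- function(model) {
  edges <- character(0)
  for (a in names(model$children)) {
    for (b in model$children[[a]]) edges <- c(edges, a, b)
  }
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(model$vocab$codes)
  if (length(edges)) g <- g + igraph::edges(edges)
  g
}

bf_reach <- function(g, a, b) {
  is.finite(igraph::distances(g, v = a, to = b, mode = "out")[1, 1])
}

bf_oracle <- function(cert, model, g = bf_graph(model), apply_reject = TRUE) {
  p1 <- cert$part1[lengths(cert$part1) > 0]
  trace <- character(0)
  if (length(p1) == 0) {
    selected <- unlist(cert$part2)[1]
    trace <- "fallback"
  } else {
    lowest <- p1[[length(p1)]]
    above <- unlist(p1[-length(p1)])
    gp <- length(lowest) == 1 &&
      all(vapply(above, function(x) bf_reach(g, lowest, x), logical(1)))
    if (gp) {
      selected <- lowest
      trace <- "general_principle"
    } else {
      e <- p1[[1]][1]
      # enumerate every Part I code as candidate origin of the
      # first-mentioned sequence, score by shortest-path remoteness
      cand <- unique(unlist(cert$part1))
      dist <- vapply(cand, function(a) {
        igraph::distances(g, v = a, to = e, mode = "out")[1, 1]
      }, numeric(1))
      cand <- cand[is.finite(dist)]
      dist <- dist[is.finite(dist)]
      line_of <- vapply(cand, function(a) {
        max(which(vapply(cert$part1, function(l) a %in% l, logical(1))))
      }, numeric(1))
      pos_of <- mapply(function(a, li) match(a, cert$part1[[li]]), cand, line_of)
      ord <- order(-dist, -line_of, pos_of, match(cand, model$vocab$codes))
      selected <- cand[ord[1]]
      trace <- "fallback"
    }
  }
  p1c <- unlist(cert$part1); p2c <- unlist(cert$part2)
  for (i in seq_len(nrow(model$promotion_pairs))) {
    pr <- model$promotion_pairs[i, ]
    if (pr$trigger %in% p2c && pr$pattern %in% p1c) {
      selected <- pr$ucd; trace <- c(trace, "promotion"); break
    }
  }
  days <- if (cert$age_unit == "days") cert$age_value else cert$age_value * 365.25
  if (days < 28 && selected %in% names(model$neonatal_map)) {
    selected <- unname(model$neonatal_map[selected])
    trace <- c(trace, "neonatal")
  }
  if (cert$year >= model$rule_change$year &&
      selected %in% names(model$rule_change$map)) {
    selected <- unname(model$rule_change$map[selected])
    trace <- c(trace, "year_rule")
  }
  n_codes <- length(p1c) + length(p2c)
  rejected <- apply_reject && trace[1] == "fallback" &&
    n_codes >= model$params$reject_min_codes
  list(ucd = if (rejected) NA_character_ else selected, rejected = rejected,
       trace = if (rejected) c(trace, "reject") else trace)
}

# a plain certificate guaranteed untouched by special rules
plain_cert <- function(model, code, year = 2005, age = 50, part2 = list()) {
  new_certificate("t", part1 = list(code), part2 = part2, sex = "M",
                  age_value = age, year = year)
}

# roots free of promotion/neonatal/year-rule involvement
neutral_roots <- function(model) {
  setdiff(model$roots,
          c(model$promotion_pairs$pattern, model$promotion_pairs$trigger,
            names(model$neonatal_map), names(model$rule_change$map)))
}
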