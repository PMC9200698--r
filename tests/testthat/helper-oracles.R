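# Independent brute-force recomputation of the load algebra, written with
# plain loops over scenario components; used as the oracle.
oracle_load_triple <- function(q, value, loq, censored) {
  cmin <- if (censored) 0 else value
  cmax <- if (censored) loq else value
  c(f_min = q[1] * cmin, f_mod = q[2] * cmin, f_high = q[3] * cmax)
}

oracle_cells_aggregates <- function(cells) {
  keys <- unique(cells[, c("event", "substance")])
  rmin <- rmod <- rhigh <- numeric(0)
  num <- c(0, 0, 0); den <- c(0, 0, 0)
  for (k in seq_len(nrow(keys))) {
    g <- cells[cells$event == keys$event[k] &
                 cells$substance == keys$substance[k], ]
    inl <- g[!g$is_stream, ]; st <- g[g$is_stream, ]
    fi <- c(0, 0, 0)
    for (i in seq_len(nrow(inl)))
      fi <- fi + oracle_load_triple(c(inl$q_min[i], inl$q_mod[i],
                                      inl$q_high[i]),
                                    inl$value[i], inl$loq[i],
                                    inl$censored[i])
    fs <- oracle_load_triple(c(st$q_min, st$q_mod, st$q_high),
                             st$value, st$loq, st$censored)
    num <- num + fi; den <- den + fs
    if (fs[3] > 0 && fs[2] > 0 && fs[1] > 0) {
      rmin <- c(rmin, fi[1] / fs[3])
      rmod <- c(rmod, fi[2] / fs[2])
      rhigh <- c(rhigh, fi[3] / fs[1])
    }
  }
  list(subst = c(mean(rmin), mean(rmod), mean(rhigh)),
       sum = unname(c(num[1] / den[3], num[2] / den[2], num[3] / den[1])))
}

random_cells <- function(n_events = 3, n_subst = 4, seed = 1,
                         censor_prob = 0.4) {
  set.seed(seed)
  rows <- list()
  for (e in seq_len(n_events)) {
    vq <- sort(stats::runif(3, 50, 500))
    for (s in seq_len(n_subst)) {
      for (i in 1:4) {
        cens <- stats::runif(1) < censor_prob
        rows[[length(rows) + 1]] <- data.frame(
          site = paste0("I", i), event = e, substance = paste0("S", s),
          q_min = vq[1] * i, q_mod = vq[2] * i, q_high = vq[3] * i,
          value = if (cens) NA else stats::runif(1, 20, 2000), loq = 20,
          censored = cens, is_stream = FALSE)
      }
      censs <- stats::runif(1) < censor_prob / 2
      qs <- stats::runif(1, 5e4, 5e5)
      rows[[length(rows) + 1]] <- data.frame(
        site = "ST", event = e, substance = paste0("S", s),
        q_min = qs, q_mod = qs, q_high = qs,
        value = if (censs) NA else stats::runif(1, 20, 500), loq = 20,
        censored = censs, is_stream = TRUE)
    }
  }
  do.call(rbind, rows)
}

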