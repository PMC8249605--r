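# Random generators for property-style tests. All loop-free by
# construction: marriages only ever pair an existing member with a fresh
# founder, so the marriage graph stays a forest.

rand_ped <- function(n_members, p_child = 0.6) {
  id <- "P1"
  fid <- NA_character_
  mid <- NA_character_
  sex <- sample(1:2, 1)
  couples <- list()
  k <- 1
  while (k < n_members) {
    k <- k + 1
    new_id <- paste0("P", k)
    if (length(couples) && stats::runif(1) < p_child) {
      cp <- couples[[sample.int(length(couples), 1)]]
      id <- c(id, new_id); fid <- c(fid, cp[1]); mid <- c(mid, cp[2])
      sex <- c(sex, sample(1:2, 1))
    } else {
      # fresh founder; usually marry into the pedigree
      partner <- NULL
      if (stats::runif(1) < 0.8 && k < n_members) {
        partner <- sample(id, 1)
        psex <- sex[match(partner, id)]
        new_sex <- 3 - psex
      } else {
        new_sex <- sample(1:2, 1)
      }
      id <- c(id, new_id); fid <- c(fid, NA); mid <- c(mid, NA)
      sex <- c(sex, new_sex)
      if (!is.null(partner)) {
        cp <- if (new_sex == 1) c(new_id, partner) else c(partner, new_id)
        couples[[length(couples) + 1]] <- cp
        # give the couple a child immediately so it is connected
        if (k < n_members) {
          k <- k + 1
          id <- c(id, paste0("P", k)); fid <- c(fid, cp[1]); mid <- c(mid, cp[2])
          sex <- c(sex, sample(1:2, 1))
        }
      }
    }
  }
  pedigree(id, fid, mid, sex)
}

# Random genotype data on a pedigree: either gene-dropped (consistent)
# or fully random (possibly Mendelian-impossible), on a random subset.
rand_data <- function(ped, db, consistent = TRUE, p_typed = 0.6) {
  if (consistent) {
    full <- gene_drop(ped, db)
    lapply(full, function(g) g[stats::runif(length(g)) < p_typed])
  } else {
    lapply(db, function(p) {
      ids <- ped$id[stats::runif(nrow(ped)) < p_typed]
      stats::setNames(vapply(ids, function(.) {
        paste(sample(names(p), 2, replace = TRUE), collapse = "/")
      }, character(1)), ids)
    })
  }
}

# Random small DVI problem with s victims and m missing persons spread
# over one or two reference families; genotypes simulated under a random
# true assignment so the data are jointly consistent.
rand_problem <- function(s, m, n_markers = 2, n_alleles = 4) {
  db <- equifreq_db(n_markers, n_alleles)
  n_fam <- if (m >= 2 && stats::runif(1) < 0.5) 2 else 1
  mp_sex <- sample(1:2, m, replace = TRUE)
  split_at <- if (n_fam == 2) sample(seq_len(m - 1), 1) else m
  mk_family <- function(mp_ids, mp_sexes, tag) {
    fa <- paste0("FA", tag); mo <- paste0("MO", tag); ref <- paste0("REF", tag)
    ped <- pedigree(id  = c(fa, mo, mp_ids, ref),
                    fid = c(NA, NA, rep(fa, length(mp_ids) + 1)),
                    mid = c(NA, NA, rep(mo, length(mp_ids) + 1)),
                    sex = c(1, 2, mp_sexes, sample(1:2, 1)))
    typed <- c(ref, if (stats::runif(1) < 0.5) mo)
    gt <- lapply(gene_drop(ped, db), function(g) g[typed])
    list(ped = ped, gt = gt, missing = mp_ids)
  }
  mps <- paste0("MP", seq_len(m))
  fams <- if (n_fam == 1) list(mk_family(mps, mp_sex, 1)) else
    list(mk_family(mps[1:split_at], mp_sex[1:split_at], 1),
         mk_family(mps[-(1:split_at)], mp_sex[-(1:split_at)], 2))
  v_sex <- sample(1:2, s, replace = TRUE)
  victims <- data.frame(id = paste0("VI", seq_len(s)), sex = v_sex)
  vgt <- lapply(db, function(p)
    stats::setNames(rep(paste0(names(p)[1], "/", names(p)[1]), s), victims$id))
  prob <- dvi_problem(victims, vgt, fams, db)
  # random true assignment: each victim independently tries to grab a
  # sex-matched unused missing person
  truth <- stats::setNames(rep("*", s), victims$id)
  for (i in seq_len(s)) {
    free <- mps[mp_sex == v_sex[i] & !mps %in% truth]
    if (length(free) && stats::runif(1) < 0.7)
      truth[i] <- free[1]
  }
  simulate_problem(prob, truth)
}

# A random pedigree + data pair small enough for the brute-force oracle:
# resamples until the genotype-combination count is tractable.
rand_oracle_case <- function(max_combos = 2e6) {
  repeat {
    ped <- rand_ped(sample(3:8, 1))
    db <- equifreq_db(1, sample(3:5, 1))
    data <- rand_data(ped, db, consistent = stats::runif(1) < 0.5)
    n <- length(db$L1)
    per <- vapply(ped$id, function(id) {
      g <- data$L1[id]
      if (is.na(g)) return(n * n)
      al <- strsplit(unname(g), "/")[[1]]
      if (al[1] == al[2]) 1 else 2
    }, numeric(1))
    if (prod(per) <= max_combos)
      return(list(ped = ped, db = db, data = data))
  }
}
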