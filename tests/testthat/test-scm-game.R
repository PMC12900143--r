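test_that("policy formulas reproduce direct evaluation", {
  p <- policy_params(z = 1, mean_demand = 1, lead_time = 1)
  expect_equal(safety_stock(p), 1)
  expect_equal(reorder_point(p), 2)

  p <- policy_params(z = 1.645, mean_demand = 7, lead_time = 1)
  expect_equal(safety_stock(p), 11.515)
  expect_equal(reorder_point(p), 18.515)
  expect_equal(eoq(p), sqrt(14))

  p <- policy_params(z = 1.645, mean_demand = 0, lead_time = 3)
  expect_equal(safety_stock(p), 0)
  expect_equal(reorder_point(p), 0)

  expect_equal(eoq(policy_params(mean_demand = 2)), 2)
  expect_equal(eoq(policy_params(mean_demand = 8, holding_cost = 4)), 2)

  expect_error(policy_params(lead_time = 0), class = "neuroplay_parameter_error")
  expect_error(policy_params(mean_demand = -1), class = "neuroplay_parameter_error")
  expect_error(policy_params(holding_cost = 0), class = "neuroplay_parameter_error")
})

test_that("policy math matches brute force on a parameter grid and is monotone", {
  set.seed(4)
  grid <- data.frame(z = runif(100, 0.5, 3), D = runif(100, 0, 20),
                     L = sample(1:5, 100, replace = TRUE),
                     K = runif(100, 0.1, 10), h = runif(100, 0.1, 10))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- policy_params(z = g$z, mean_demand = g$D, lead_time = g$L,
                       order_cost = g$K, holding_cost = g$h)
    expect_equal(safety_stock(p), g$z * g$D * g$L, tolerance = 1e-12)
    expect_equal(reorder_point(p), g$z * g$D * g$L + g$D * g$L,
                 tolerance = 1e-12)
    expect_equal(eoq(p), sqrt(2 * g$D * g$K / g$h), tolerance = 1e-12)
  }
  # monotonicity: eoq in D and K up, in h down; ROP in z, D, L up
  base <- list(z = 1.5, D = 5, L = 2, K = 2, h = 2)
  pp <- function(l) policy_params(z = l$z, mean_demand = l$D, lead_time = l$L,
                                  order_cost = l$K, holding_cost = l$h)
  for (d in c(6, 8, 12)) expect_gte(eoq(pp(modifyList(base, list(D = d)))),
                                    eoq(pp(base)))
  expect_gte(eoq(pp(modifyList(base, list(K = 5)))), eoq(pp(base)))
  expect_lte(eoq(pp(modifyList(base, list(h = 5)))), eoq(pp(base)))
  expect_gte(reorder_point(pp(modifyList(base, list(z = 2)))),
             reorder_point(pp(base)))
  expect_gte(reorder_point(pp(modifyList(base, list(L = 3)))),
             reorder_point(pp(base)))
})

test_that("npc ordering triggers inclusively at the reorder point", {
  p <- policy_params(z = 1.645, mean_demand = 7, lead_time = 1)
  mk <- function(name, inv, transit = 0) {
    list(name = name, inventory = inv,
         in_transit = tibble::tibble(arrival_day = 2L, units = transit))
  }
  expect_equal(npc_order(mk("distributor", 100), p), 0L)
  expect_equal(npc_order(mk("distributor", 10), p), 4L)  # ceil(sqrt(14))
  expect_equal(npc_order(mk("manufacturer", 18.515), p), 4L)  # boundary
  # in-transit stock counts toward the position
  expect_equal(npc_order(mk("distributor", 10, transit = 100), p), 0L)
  expect_error(npc_order(mk("farmer", 0), p), class = "neuroplay_policy_error")
  expect_error(npc_order(mk("customer", 0), p), class = "neuroplay_policy_error")
})

test_that("a simulated day conserves inventory and records lost sales", {
  cfg <- game_config()
  st <- new_game(cfg)
  r1 <- step_day(st, 5)
  ret <- r1$record[r1$record$actor == "retailer", ]
  expect_equal(ret$demand_faced, 5)
  expect_equal(ret$sales, 5)
  expect_equal(ret$lost_sales, 0)
  expect_equal(ret$end_inventory, 5)

  # empty stock loses the full demand
  cfg0 <- game_config(start_inventory = c(retailer = 0, distributor = 20,
                                          manufacturer = 20))
  r <- step_day(new_game(cfg0), 0)$record
  ret <- r[r$actor == "retailer", ]
  expect_equal(ret$sales, 0)
  expect_equal(ret$lost_sales, r$demand_faced[r$actor == "retailer"])

  # scripted demand: day 3 carries the peak of 12
  res <- run_scenario(game_config())
  led <- res$ledger[res$ledger$actor == "retailer", ]
  expect_equal(led$demand_faced, c(5, 8, 12, 8, 8, 5, 3))
  expect_equal(led$start_inventory[1], 10)

  expect_error(step_day(res$ledger, 1))
  st <- new_game(game_config(demand = c(1)))
  st <- step_day(st, 0)$state
  expect_error(step_day(st, 0), class = "neuroplay_scenario_complete")
})

test_that("ledgers satisfy conservation and a brute-force replay", {
  res <- run_scenario(game_config())
  l <- res$ledger
  expect_true(all(l$end_inventory == l$start_inventory + l$arrivals - l$sales))
  expect_true(all(l$sales == pmin(l$demand_faced,
                                  l$start_inventory + l$arrivals)))
  expect_true(all(l$lost_sales == l$demand_faced - l$sales))
  expect_true(all(l$sales >= 0 & l$lost_sales >= 0 & l$end_inventory >= 0))

  # replay oracle: arrivals must equal the upstream actor's sales one
  # lead time earlier, and inventories must chain day over day
  chain <- c(retailer = "distributor", distributor = "manufacturer",
             manufacturer = "farmer")
  for (a in names(chain)) {
    la <- l[l$actor == a, ]
    up <- l[l$actor == chain[[a]], ]
    for (d in la$day) {
      expected <- if (d - 1 >= 1) up$sales[up$day == d - 1] else 0
      expect_equal(la$arrivals[la$day == d], expected)
    }
    expect_equal(la$start_inventory[-1], head(la$end_inventory, -1))
  }
  # cumulative demand splits into sales plus lost sales
  tot <- aggregate(cbind(demand_faced, sales, lost_sales) ~ actor, l, sum)
  expect_equal(tot$demand_faced, tot$sales + tot$lost_sales)
})

test_that("zero-order policy loses all demand beyond starting stock", {
  cfg <- game_config()
  res <- run_scenario(cfg, player_policy = rep(0, 7))
  led <- res$ledger[res$ledger$actor == "retailer", ]
  # brute-force: sell from the initial 10 units until exhausted
  inv <- 10; lost <- 0
  for (d in cfg$demand) {
    s <- min(d, inv); inv <- inv - s; lost <- lost + d - s
  }
  expect_equal(sum(led$lost_sales), lost)
  expect_equal(sum(led$sales), 10)

  res0 <- run_scenario(game_config(demand = rep(0, 5)))
  led0 <- res0$ledger[res0$ledger$actor == "retailer", ]
  expect_equal(sum(led0$revenue), 0)
  expect_equal(sum(led0$lost_sales), 0)
})

test_that("communication phase discloses but never alters dynamics", {
  a <- run_scenario(game_config(phase = "no_communication"))
  b <- run_scenario(game_config(phase = "communication"))
  core <- c("day", "actor", "demand_faced", "sales", "lost_sales",
            "order_placed", "arrivals", "start_inventory", "end_inventory",
            "revenue", "holding_cost_incurred")
  expect_identical(a$ledger[core], b$ledger[core])
  expect_true(all(is.na(a$ledger$disclosed_inventory)))
  disc <- b$ledger$disclosed_inventory[b$ledger$actor == "distributor"]
  expect_true(all(!is.na(disc)))

  # determinism: identical config and policy give identical ledgers
  expect_identical(run_scenario(game_config())$ledger,
                   run_scenario(game_config())$ledger)
})

test_that("bullwhip ratio matches its variance definition", {
  d <- c(5, 8, 12, 8, 8, 5, 3)
  expect_equal(bullwhip_ratio(d, d), 1)
  expect_equal(bullwhip_ratio(rep(4, 7), d), 0)
  expect_error(bullwhip_ratio(d, rep(2, 7)),
               class = "neuroplay_undefined_ratio_error")
  expect_error(bullwhip_ratio(1, 1), class = "neuroplay_parameter_error")
  pvar <- function(x) mean((x - mean(x))^2)
  set.seed(9)
  o <- rpois(7, 5); dd <- rpois(7, 5) + c(1:7)
  expect_equal(bullwhip_ratio(o, dd), pvar(o) / pvar(dd))
})
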