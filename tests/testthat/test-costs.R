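disc <- discount_settings(0.035)

test_that("identical arms produce zero cost increments", {
  sg <- make_rwt_subgroup(direct_early = 100000, direct_delayed = 100000)
  sg$costs$incurrence_time_delayed <- sg$costs$incurrence_time_early
  cb <- subgroup_costs(sg, disc)$per_patient
  expect_equal(cb$delta_direct, 0)
  expect_equal(cb$delta_total_societal, 0)
})

test_that("earlier spending costs more in present value", {
  sg <- make_rwt_subgroup(t_early = 0, t_delayed = 2,
                          direct_early = 100000, direct_delayed = 100000)
  cb <- subgroup_costs(sg, disc)$per_patient
  expect_equal(cb$delta_direct, 100000 * (1 - 1.035^(-2)))
  expect_gt(cb$delta_direct, 0)
})

test_that("indirect savings drive societal below payer totals", {
  sg <- make_rwt_subgroup(
    direct_early = 110000, direct_delayed = 100000,
    indirect_patient_early = 5000, indirect_patient_delayed = 40000,
    indirect_caregiver_early = 2000, indirect_caregiver_delayed = 20000)
  cb <- subgroup_costs(sg, disc)$per_patient
  expect_lt(cb$delta_total_societal, cb$delta_total_payer)
  expect_equal(cb$delta_total_payer, cb$delta_direct)
  expect_equal(cb$delta_total_societal,
               cb$delta_direct + cb$delta_indirect_patient +
                 cb$delta_indirect_caregiver)
})

test_that("missed-surgery counterfactual keeps indirect losses", {
  u <- utility_profile(u_post_early = 0.8, u_missed = 0.4)
  sg <- subgroup_parameters(
    "AMS", 10, u, timeline(0, 15, 15, 20),
    cost_set(direct_early = 100000, direct_delayed = 0,
             indirect_patient_early = 10000,
             indirect_patient_delayed = 50000,
             incurrence_time_early = 0, incurrence_time_delayed = 5))
  cb <- subgroup_costs(sg, disc)$per_patient
  expect_equal(cb$delta_direct, 100000)
  expect_equal(cb$delta_indirect_patient,
               10000 - 50000 * 1.035^(-5))
})

test_that("lifesaving zeroes every counterfactual component", {
  u <- utility_profile(u_post_early = 0.8)
  sg <- subgroup_parameters(
    "MA", 10, u, timeline(0.5, 0.5, 0.5, 20),
    cost_set(direct_early = 100000, direct_delayed = 80000,
             indirect_patient_delayed = 50000,
             indirect_caregiver_delayed = 25000,
             incurrence_time_early = 0.5, incurrence_time_delayed = 1))
  cb <- subgroup_costs(sg, disc)$per_patient
  expect_equal(cb$delta_direct, 100000 * 1.035^(-0.5))
  expect_equal(cb$delta_indirect_patient, 0)
  expect_equal(cb$delta_indirect_caregiver, 0)
})

test_that("population costs are linear in patient count", {
  sg1 <- make_rwt_subgroup(n = 1, direct_early = 123456,
                           direct_delayed = 98765)
  sg7 <- make_rwt_subgroup(n = 7, direct_early = 123456,
                           direct_delayed = 98765)
  expect_equal(subgroup_costs(sg7, disc)$population$delta_direct,
               7 * subgroup_costs(sg1, disc)$population$delta_direct)
})

test_that("zero-rate limit reduces to undiscounted differences", {
  sg <- make_rwt_subgroup(direct_early = 150000, direct_delayed = 90000,
                          indirect_patient_early = 1000,
                          indirect_patient_delayed = 4000)
  cb <- subgroup_costs(sg, discount_settings(0))$per_patient
  expect_equal(cb$delta_direct, 60000)
  expect_equal(cb$delta_indirect_patient, -3000)
})
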