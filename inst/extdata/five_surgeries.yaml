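schema_version: 1
discount:
  annual_rate: 0.035
economy:
  gdp_per_capita: 56000.0
  wtp_threshold: 56000.0
  currency_label: EGP
cohorts:
- name: open_heart_surgery
  subgroups:
  - kind: RWT
    scenario: reduced_wait
    n_patients: 6000.0
    utilities:
      u_wait: 0.6
      u_post_early: 0.8
      u_post_delayed: 0.78
    timeline:
      t_early: 0.1
      t_delayed: 1.5
      t_death_counterfactual: 18.0
      t_death_early: 20.0
    costs:
      direct_early: 200000.0
      direct_delayed: 150000.0
      indirect_patient_early: 20000.0
      indirect_patient_delayed: 40000.0
      indirect_caregiver_early: 10000.0
      indirect_caregiver_delayed: 20000.0
      incurrence_time_early: 0.1
      incurrence_time_delayed: 1.5
  - kind: AMS
    scenario: missed_surgery
    n_patients: 800.0
    utilities:
      u_post_early: 0.8
      u_missed: 0.45
    timeline:
      t_early: 0.1
      t_delayed: 10.0
      t_death_counterfactual: 10.0
      t_death_early: 20.0
    costs:
      direct_early: 200000.0
      direct_delayed: 0.0
      indirect_patient_early: 20000.0
      indirect_patient_delayed: 80000.0
      indirect_caregiver_early: 10000.0
      indirect_caregiver_delayed: 40000.0
      incurrence_time_early: 0.1
      incurrence_time_delayed: 10.0
  - kind: MA
    scenario: lifesaving
    n_patients: 400.0
    utilities:
      u_post_early: 0.8
    timeline:
      t_early: 0.1
      t_delayed: 0.1
      t_death_counterfactual: 0.1
      t_death_early: 18.0
    costs:
      direct_early: 200000.0
      direct_delayed: 0.0
      indirect_patient_early: 0.0
      indirect_patient_delayed: 0.0
      indirect_caregiver_early: 0.0
      indirect_caregiver_delayed: 0.0
      incurrence_time_early: 0.1
      incurrence_time_delayed: 0.1
- name: cardiac_catheterization
  subgroups:
  - kind: RWT
    scenario: reduced_wait
    n_patients: 25000.0
    utilities:
      u_wait: 0.65
      u_post_early: 0.78
      u_post_delayed: 0.77
    timeline:
      t_early: 0.1
      t_delayed: 1.2
      t_death_counterfactual: 20.0
      t_death_early: 21.0
    costs:
      direct_early: 60000.0
      direct_delayed: 40000.0
      indirect_patient_early: 10000.0
      indirect_patient_delayed: 15000.0
      indirect_caregiver_early: 5000.0
      indirect_caregiver_delayed: 8000.0
      incurrence_time_early: 0.1
      incurrence_time_delayed: 1.2
  - kind: MA
    scenario: lifesaving
    n_patients: 300.0
    utilities:
      u_post_early: 0.78
    timeline:
      t_early: 0.1
      t_delayed: 0.1
      t_death_counterfactual: 0.1
      t_death_early: 20.0
    costs:
      direct_early: 60000.0
      direct_delayed: 0.0
      indirect_patient_early: 0.0
      indirect_patient_delayed: 0.0
      indirect_caregiver_early: 0.0
      indirect_caregiver_delayed: 0.0
      incurrence_time_early: 0.1
      incurrence_time_delayed: 0.1
- name: cochlear_implantation
  subgroups:
  - kind: RWT
    scenario: reduced_wait
    n_patients: 1200.0
    utilities:
      u_wait: 0.35
      u_post_early: 0.75
      u_post_delayed: 0.65
    timeline:
      t_early: 0.2
      t_delayed: 2.0
      t_death_counterfactual: 60.0
      t_death_early: 60.0
    costs:
      direct_early: 350000.0
      direct_delayed: 320000.0
      indirect_patient_early: 100000.0
      indirect_patient_delayed: 250000.0
      indirect_caregiver_early: 80000.0
      indirect_caregiver_delayed: 200000.0
      incurrence_time_early: 0.2
      incurrence_time_delayed: 2.0
  - kind: AMS
    scenario: missed_surgery
    n_patients: 300.0
    utilities:
      u_post_early: 0.75
      u_missed: 0.35
    timeline:
      t_early: 0.2
      t_delayed: 55.0
      t_death_counterfactual: 55.0
      t_death_early: 60.0
    costs:
      direct_early: 350000.0
      direct_delayed: 0.0
      indirect_patient_early: 100000.0
      indirect_patient_delayed: 500000.0
      indirect_caregiver_early: 80000.0
      indirect_caregiver_delayed: 400000.0
      incurrence_time_early: 0.2
      incurrence_time_delayed: 10.0
- name: retinal_surgery
  subgroups:
  - kind: RWT
    scenario: reduced_wait
    n_patients: 12000.0
    utilities:
      u_wait: 0.62
      u_post_early: 0.72
      u_post_delayed: 0.71
    timeline:
      t_early: 0.1
      t_delayed: 1.1
      t_death_counterfactual: 24.0
      t_death_early: 24.0
    costs:
      direct_early: 40000.0
      direct_delayed: 15000.0
      indirect_patient_early: 6000.0
      indirect_patient_delayed: 7000.0
      indirect_caregiver_early: 2000.0
      indirect_caregiver_delayed: 2400.0
      incurrence_time_early: 0.1
      incurrence_time_delayed: 1.1
  - kind: AMS
    scenario: missed_surgery
    n_patients: 500.0
    utilities:
      u_post_early: 0.72
      u_missed: 0.6
    timeline:
      t_early: 0.1
      t_delayed: 20.0
      t_death_counterfactual: 20.0
      t_death_early: 24.0
    costs:
      direct_early: 40000.0
      direct_delayed: 0.0
      indirect_patient_early: 6000.0
      indirect_patient_delayed: 30000.0
      indirect_caregiver_early: 2000.0
      indirect_caregiver_delayed: 10000.0
      incurrence_time_early: 0.1
      incurrence_time_delayed: 20.0
- name: joint_replacement
  subgroups:
  - kind: RWT
    scenario: reduced_wait
    n_patients: 9000.0
    utilities:
      u_wait: 0.55
      u_post_early: 0.75
      u_post_delayed: 0.74
    timeline:
      t_early: 0.1
      t_delayed: 1.8
      t_death_counterfactual: 15.0
      t_death_early: 15.0
    costs:
      direct_early: 120000.0
      direct_delayed: 100000.0
      indirect_patient_early: 15000.0
      indirect_patient_delayed: 25000.0
      indirect_caregiver_early: 8000.0
      indirect_caregiver_delayed: 13000.0
      incurrence_time_early: 0.1
      incurrence_time_delayed: 1.8
  - kind: AMS
    scenario: missed_surgery
    n_patients: 600.0
    utilities:
      u_post_early: 0.75
      u_missed: 0.5
    timeline:
      t_early: 0.1
      t_delayed: 12.0
      t_death_counterfactual: 12.0
      t_death_early: 15.0
    costs:
      direct_early: 120000.0
      direct_delayed: 0.0
      indirect_patient_early: 15000.0
      indirect_patient_delayed: 35000.0
      indirect_caregiver_early: 8000.0
      indirect_caregiver_delayed: 15000.0
      incurrence_time_early: 0.1
      incurrence_time_delayed: 12.0

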