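id,strategy,baseline,lower,upper,family,units,label
cost_lr_hospital_y1,,10147.18,2971.96,17322.39,lognormal,USD,Cost of local recurrence hospitalization (first year)
cost_lr_outpatient_y1,,3728.43,2305.50,5151.35,lognormal,USD,Cost of local recurrence outpatient (first year)
cost_met_hospital,,10652.42,9233.85,12070.99,lognormal,USD,Cost of distant metastasis hospitalization per year
cost_met_outpatient,,2984.55,2649.14,3319.96,lognormal,USD,Cost of distant metastasis outpatient per year
cost_predeath_hospital,,3585.82,2533.61,4638.03,lognormal,USD,Cost of hospitalization for 3 months before death
cost_predeath_outpatient,,874.56,713.96,1035.15,lognormal,USD,Cost of outpatient for 3 months before death
cost_hospital_y1,MAST_RECON,10221.30,9192.74,11249.86,lognormal,USD,Cost of MAST+RECON hospitalization (first year)
cost_outpatient_y1,MAST_RECON,6070.98,5233.55,6908.42,lognormal,USD,Cost of MAST+RECON outpatient (first year)
cost_hospital_y1,BCT,7475.54,4659.50,10291.58,lognormal,USD,Cost of BCT hospitalization (first year)
cost_outpatient_y1,BCT,6905.61,6051.87,7759.35,lognormal,USD,Cost of BCT outpatient (first year)
cost_hospital_y1,MAST,6630.24,6114.63,7145.85,lognormal,USD,Cost of MAST hospitalization (first year)
cost_outpatient_y1,MAST,4210.88,3608.80,4812.97,lognormal,USD,Cost of MAST outpatient (first year)
cost_followup_annual,MAST_RECON,1448.12,1166.11,1730.13,lognormal,USD,Annual cost of follow-up for MAST+RECON
cost_followup_annual,BCT,1198.82,961.66,1435.99,lognormal,USD,Annual cost of follow-up for BCT
cost_followup_annual,MAST,770.22,770.22,1090.77,lognormal,USD,Annual cost of follow-up for MAST
cost_transport_y1,MAST_RECON,253.97,203.17,304.76,lognormal,USD,Transportation cost of MAST+RECON
cost_lost_work_y1,MAST_RECON,1202.54,962.03,1443.04,lognormal,USD,Cost of losing work of MAST+RECON
cost_transport_y1,BCT,219.34,175.47,263.20,lognormal,USD,Transportation cost of BCT
cost_lost_work_y1,BCT,997.85,798.28,1197.42,lognormal,USD,Cost of losing work of BCT
cost_transport_y1,MAST,230.88,184.70,277.06,lognormal,USD,Transportation cost of MAST
cost_lost_work_y1,MAST,1125.78,900.62,1350.93,lognormal,USD,Cost of losing work of MAST
utility_lr_y1,,0.779,0.641,0.917,beta,utility,Utility of local recurrence (first year)
utility_metastasis,,0.737,0.657,0.817,beta,utility,Utility of distant metastasis
utility_dfs_y1,MAST_RECON,0.868,0.694,1,beta,utility,Utility of disease-free for MAST+RECON (first year)
utility_dfs_plus,MAST_RECON,0.933,0.746,1,beta,utility,Utility of disease-free for MAST+RECON (subsequent year)
utility_dfs_y1,BCT,0.872,0.823,0.921,beta,utility,Utility of disease-free for BCT (first year)
utility_dfs_plus,BCT,0.923,0.903,0.943,beta,utility,Utility of disease-free for BCT (subsequent year)
utility_dfs_y1,MAST,0.785,0.729,0.842,beta,utility,Utility of disease-free for MAST (first year)
utility_dfs_plus,MAST,0.900,0.883,0.918,beta,utility,Utility of disease-free for MAST (subsequent year)
p_dfs_to_lr,MAST_RECON,0.002908,0.002326,0.003489,beta,probability,Local recurrence of MAST+RECON
p_dfs_to_met,MAST_RECON,0.016702,0.013362,0.020042,beta,probability,Distant metastasis of MAST+RECON
p_lr_to_met,MAST_RECON,0.000000,0.000000,0.100000,beta,probability,Distant metastasis after local recurrence of MAST+RECON
p_met_to_death,MAST_RECON,0.103557,0.082845,0.124268,beta,probability,Death after distant metastasis of MAST+RECON
p_dfs_to_lr,BCT,0.002679,0.002143,0.003215,beta,probability,Local recurrence of BCT
p_dfs_to_met,BCT,0.009889,0.007911,0.011867,beta,probability,Distant metastasis of BCT
p_lr_to_met,BCT,0.201328,0.161062,0.241593,beta,probability,Distant metastasis after local recurrence of BCT
p_met_to_death,BCT,0.016491,0.013193,0.019789,beta,probability,Death after distant metastasis of BCT
p_dfs_to_lr,MAST,0.004019,0.003215,0.004823,beta,probability,Local recurrence of MAST
p_dfs_to_met,MAST,0.011288,0.009030,0.013545,beta,probability,Distant metastasis of MAST
p_lr_to_met,MAST,1.000000,0.800000,1.000000,beta,probability,Distant metastasis after local recurrence of MAST
p_met_to_death,MAST,0.335161,0.268129,0.402193,beta,probability,Death after distant metastasis of MAST
discount_rate,,0.03,0,0.05,constant,rate-fraction,Annual discount rate
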