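name: chronic_infusion
constants:
  gas_constant: 0.0623637
  temperature: 310.149999999999977
  pKa_carbonic: 6.1
  Kh_co2: 0.03
compartments:
- id: arteries
  rest_volume_V0: 100.0
  rest_pressure_P0: 95.0
  rigid: yes
- id: arterioles
  rest_volume_V0: 30.0
  rest_pressure_P0: 70.0
  rigid: yes
- id: capillaries
  rest_volume_V0: 30.0
  rest_pressure_P0: 30.0
  rigid: yes
- id: veins
  rest_volume_V0: 120.0
  rest_pressure_P0: 7.0
  rigid: yes
- id: ventricles
  rest_volume_V0: 60.0
  rest_pressure_P0: 9.6876
  compliance_kappa: 8.78415745442128
- id: ECS
  rest_volume_V0: 600.0
  rest_pressure_P0: 12.097200000000001
  compliance_kappa: 1.0
- id: PVS
  rest_volume_V0: 30.0
  rest_pressure_P0: 12.695600000000001
  compliance_kappa: 0.2
- id: SAS
  rest_volume_V0: 150.0
  rest_pressure_P0: 8.084099999999999
  compliance_kappa: 2.0
arcs:
- id: Q1
  kind: boundary
  from: inlet
  to: arteries
  resistance_alpha: 0.0025
- id: Q2
  kind: luminal
  from: arteries
  to: arterioles
  resistance_alpha: 0.0125
- id: Q3
  kind: luminal
  from: arterioles
  to: capillaries
  resistance_alpha: 0.02
- id: Q4
  kind: luminal
  from: capillaries
  to: veins
  resistance_alpha: 0.0115
- id: Q5
  kind: boundary
  from: veins
  to: outlet
  resistance_alpha: 0.001
- id: Q6
  kind: luminal
  from: PVS
  to: SAS
  resistance_alpha: 0.05
- id: J7
  kind: starling
  from: arterioles
  to: ventricles
  LpA: 3.0e-05
  one_way: yes
  sigma:
    albumin: 1.0
    Na: 0.01
    K: 0.01
    Cl: 0.01
    HCO3: 0.01
    glucose: 0.2
    sucrose: 0.2
    mannitol: 1.0
    tracer: 1.0
  pump:
    Na: 0.28
    Cl: 0.28
    mannitol: 0.0
- id: J8
  kind: starling
  from: capillaries
  to: PVS
  LpA: 0.01
  sigma:
    albumin: 1.0
    Na: 1.0
    K: 1.0
    Cl: 1.0
    HCO3: 1.0
    glucose: 1.0
    sucrose: 1.0
    mannitol: 1.0
    tracer: 1.0
  pump:
    Na: 0.9
    Cl: 0.9
- id: Q9
  kind: darcy
  from: PVS
  to: ECS
  resistance_alpha: 1.0
- id: J10
  kind: starling
  from: ECS
  to: ventricles
  LpA: 0.3
  sigma:
    albumin: 1.0
    Na: 0.0
    K: 0.0
    Cl: 0.0
    HCO3: 0.0
    glucose: 0.0
    sucrose: 0.0
    mannitol: 1.0
    tracer: 1.0
    fgf2: 0.017127430156503
- id: Q11
  kind: luminal
  from: ventricles
  to: SAS
  resistance_alpha: 2.0
- id: J12
  kind: starling
  from: SAS
  to: veins
  LpA: 5.0
  one_way: yes
  sigma:
    albumin: 0.0
    Na: 0.0
    K: 0.0
    Cl: 0.0
    HCO3: 0.0
    glucose: 0.0
    sucrose: 0.0
    mannitol: 0.0
    tracer: 0.0
    fgf2: 0.0
boundaries:
  inlet_pressure: 100.0
  outlet_pressure: 5.0
  arterial_concentrations:
    albumin: 0.6
    Na: 158.0
    K: 4.0
    Cl: 122.0
    HCO3: 28.0
    glucose: 5.0
    sucrose: 0.0
    mannitol: 2.2
    tracer: 0.0
    fgf2: 0.0
metabolic:
  k_gluc: 0.0
  nu_water_per_glucose: 0.10809
  direct_G_override: 0.2
initial:
  concentrations:
    ventricles:
      Na: 160.0
      Cl: 160.0
    SAS:
      Na: 160.0
      Cl: 160.0
    ECS:
      Na: 150.0
      Cl: 150.0
    PVS:
      Na: 150.0
      Cl: 150.0
species:
- name: albumin
  dissociation_n: 1.0
  osmotic_coeff_phi: 1.0
- name: Na
  dissociation_n: 1.0
  osmotic_coeff_phi: 1.0
- name: K
  dissociation_n: 1.0
  osmotic_coeff_phi: 1.0
- name: Cl
  dissociation_n: 1.0
  osmotic_coeff_phi: 1.0
- name: HCO3
  dissociation_n: 1.0
  osmotic_coeff_phi: 1.0
- name: glucose
  dissociation_n: 1.0
  osmotic_coeff_phi: 1.0
- name: sucrose
  dissociation_n: 1.0
  osmotic_coeff_phi: 1.0
- name: mannitol
  dissociation_n: 1.0
  osmotic_coeff_phi: 1.0
- name: tracer
  dissociation_n: 1.0
  osmotic_coeff_phi: 1.0
- name: fgf2
  dissociation_n: 1.0
  osmotic_coeff_phi: 1.0
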