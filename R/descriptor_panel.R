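# The 2D descriptor panel: substructure-count descriptors evaluated as
# SMARTS matches (unique occurrences). Names become feature names with a
# "n_" prefix. The panel deliberately over-covers the property families
# that drive excited-state proton transfer: H-bond donors/acceptors,
# acidity/basicity proxies, conjugation, oxygen content, charge.
smarts_panel <- c(
  # element counts
  atom_B = "[#5]", atom_C = "[#6]", atom_N = "[#7]", atom_O = "[#8]",
  atom_F = "[#9]", atom_Si = "[#14]", atom_P = "[#15]", atom_S = "[#16]",
  atom_Cl = "[#17]", atom_Br = "[#35]", atom_I = "[#53]",
  halogen = "[F,Cl,Br,I]",
  heteroatom = "[!#6;!#1]",
  # aromatic atoms
  arom_C = "c", arom_N = "n", arom_O = "o", arom_S = "s",
  arom_any = "a", arom_hetero = "[a;!#6]", arom_NH = "[nH]",
  arom_N_basic = "[nX2]", arom_CH = "[cH]", arom_C_subst = "[cH0]",
  # hybridization / hydrogen counts on carbon
  C_sp3 = "[CX4]", C_sp2 = "[CX3]", C_sp = "[CX2]",
  CH3 = "[CH3]", CH2 = "[CH2]", CH1 = "[CX4H1]", C_quart = "[CX4H0]",
  # nitrogen environments
  N_sp3 = "[NX3]", N_sp2 = "[#7X2]", N_sp = "[NX1]",
  N_primary_amine = "[NX3H2;!$(NC=O)]",
  N_secondary_amine = "[NX3H1;!$(NC=O)]([#6])[#6]",
  N_tertiary_amine = "[NX3H0;!$(NC=O);!$(N=O)]([#6])([#6])[#6]",
  N_aromatic_amine = "c[NX3]",
  N_basic = "[NX3;!$(NC=O);!$(N=*);!$(N[a])]",
  N_quaternary = "[NX4+]",
  N_amide = "[NX3][CX3](=[OX1])",
  NH_any = "[#7;!H0]",
  # oxygen environments
  O_sp3 = "[OX2]", O_sp2 = "[OX1]",
  OH_any = "[OX2H]", OH_alcohol = "[CX4][OX2H]", OH_phenol = "c[OX2H]",
  O_ether = "[OD2]([#6])[#6]", O_arom_ether = "c[OX2][CX4]",
  # sulfur / phosphorus
  SH_thiol = "[SX2H]", S_thioether = "[SX2]([#6])[#6]",
  S_sulfoxide = "[SX3](=O)", S_sulfone = "[SX4](=O)(=O)",
  sulfonamide = "[SX4](=O)(=O)[NX3]", P_oxide = "[PX4](=O)",
  # carbonyl family
  carbonyl = "[CX3]=[OX1]",
  carboxylic_acid = "[CX3](=O)[OX2H1]",
  carboxylate = "[CX3](=O)[O-]",
  ester = "[CX3](=O)[OX2][#6]",
  amide = "[CX3](=O)[NX3]",
  aldehyde = "[CX3H1](=O)[#6]",
  ketone = "[#6][CX3](=O)[#6]",
  urea = "[NX3][CX3](=O)[NX3]",
  carbamate = "[OX2][CX3](=O)[NX3]",
  aryl_ketone = "c[CX3](=O)",
  conjugated_carbonyl = "[CX3]=[CX3][CX3]=[OX1]",
  # other groups
  nitrile = "[CX2]#[NX1]",
  nitro = "[NX3+](=O)[O-]",
  azo = "[#7X2]=[#7X2]",
  imine = "[CX3]=[NX2]",
  hydrazone = "[CX3]=[NX2][NX3]",
  oxime = "[CX3]=[NX2][OX2H]",
  enamine = "[CX3]=[CX3][NX3]",
  enol_ether = "[CX3]=[CX3][OX2]",
  acetal = "[CX4]([OX2])[OX2]",
  peroxide = "[OX2][OX2]",
  disulfide = "[SX2][SX2]",
  CF3 = "[CX4](F)(F)F",
  alkene = "[CX3]=[CX3]",
  alkyne = "[CX2]#[CX2]",
  diene = "[CX3]=[CX3][CX3]=[CX3]",
  styrene = "c[CX3]=[CX3]",
  halide_aromatic = "c[F,Cl,Br,I]",
  halide_aliphatic = "[CX4][F,Cl,Br,I]",
  methoxy = "[OX2][CH3]",
  tbutyl = "[CX4]([CH3])([CH3])[CH3]",
  double_bond = "*=*",
  triple_bond = "*#*",
  # ring membership
  ring_atom = "[R]", ring_atom_2plus = "[R2]", arom_fused = "[aR2]",
  N_in_ring = "[#7;R]", O_in_ring = "[#8;R]", S_in_ring = "[#16;R]",
  hetero_in_ring = "[!#6;!#1;R]",
  ring3 = "*1~*~*1", ring4 = "*1~*~*~*1", ring5 = "*1~*~*~*~*1",
  ring6 = "*1~*~*~*~*~*1", ring7 = "*1~*~*~*~*~*~*1",
  benzene_ring = "c1ccccc1", pyridine_ring = "n1ccccc1",
  furan_ring = "o1cccc1", thiophene_ring = "s1cccc1",
  pyrrole_ring = "[nH]1cccc1",
  arom5_ring = "[a]1[a][a][a][a]1",
  biaryl_link = "[c;R]-!@[c;R]",
  ring_assembly_link = "[R]!@[R]",
  # H-bonding / proton-transfer environments
  HBD = "[#7,#8,#16;!H0]",
  HBA_N = "[#7;X1,X2,X3;!$([N+]);!$([NX3][CX3]=[OX1])]",
  HBA_O = "[#8;X1,X2]",
  ortho_hydroxy_aryl = "[OX2H]c1ccccc1",
  esipt_donor_acceptor = "[OX2H]c1ccccc1[#6]~[#7X2]",
  salicyl_carbonyl = "[OX2H]c1ccccc1[CX3]=[OX1]",
  amino_aryl_imine = "[NX3!H0]c1ccccc1[#6]~[#7X2]",
  intramol_OHN_5 = "[OX2H][#6]~[#6]~[#7X2]",
  intramol_OHO = "[OX2H][#6]~[#6]~[#6]=[OX1]",
  # acidity / basicity proxies
  acidic_group = "[$([CX3](=O)[OX2H1]),$([SX4](=O)(=O)[OX2H]),$(c[OX2H]),$([PX4](=O)[OX2H])]",
  basic_group = "[$([NX3;!$(NC=O);!$(N=*);!$(N[a]);!$(N[SX4])])]",
  tetrazole = "c1nnn[nH]1",
  # charge
  pos_charge = "[+,+2,+3]", neg_charge = "[-,-2,-3]",
  zwitter_N = "[NX4+,NX3+]",
  # chains and branching
  chain2 = "[CX4][CX4]", chain3 = "[CX4][CX4][CX4]",
  chain4 = "[CX4][CX4][CX4][CX4]",
  branch = "[*;!R]([*;!R])([*;!R])[*;!R]",
  rotatable = "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]",
  # paired-heteroatom environments
  NCN = "[#7]~[#6]~[#7]", OCO = "[#8]~[#6]~[#8]",
  NCO = "[#7]~[#6]~[#8]", NN = "[#7]~[#7]", NO = "[#7]~[#8]",
  SC = "[#16]~[#6]", aro_adj_hetero = "[a][!#6;!#1]",
  carbonyl_alpha_H = "[CX4;!H0][CX3]=[OX1]",
  vinylogous_acid = "[OX2H][CX3]=[CX3]",
  michael_acceptor = "[CX3]=[CX3][$([CX3]=[OX1]),$([CX2]#[NX1]),$([SX4](=O)=O),$([NX3+](=O)[O-])]"
)
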