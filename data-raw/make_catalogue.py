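"""Generate the embedded X-ray emission-line catalogue (inst/extdata/xray_lines.csv).

Run once against xraylib (conda-forge); the committed CSV is the package's
source of truth at run time -- xraylib is NOT a run-time dependency.

Relative intensities are Kissel fluorescence cross sections at a 20 keV
reference excitation, normalized to the principal line (= 1) within each
(element, series) group.
"""
import xraylib as xl
import csv

K_ELEMENTS = {15:'P',16:'S',17:'Cl',19:'K',20:'Ca',22:'Ti',23:'V',24:'Cr',
              25:'Mn',26:'Fe',27:'Co',28:'Ni',29:'Cu',30:'Zn'}
L_ELEMENTS = {57:'La',58:'Ce',59:'Pr',60:'Nd',61:'Pm',62:'Sm',63:'Eu',64:'Gd',
              65:'Tb',66:'Dy',67:'Ho',68:'Er',69:'Tm',70:'Yb',71:'Lu'}
INIT = {'K': xl.K_SHELL, 'L1': xl.L1_SHELL, 'L2': xl.L2_SHELL, 'L3': xl.L3_SHELL}
FINAL = ['L1','L2','L3','M1','M2','M3','M4','M5',
         'N1','N2','N3','N4','N5','N6','N7',
         'O1','O2','O3','O4','O5','O6','O7','P1','P2','P3','P4','P5']
E_REF = 20.0  # keV

def series_lines(Z, series):
    rows = []
    shells = ['K'] if series == 'K' else ['L1', 'L2', 'L3']
    for ini in shells:
        edge = xl.EdgeEnergy(Z, INIT[ini])
        for fin in FINAL:
            macro = getattr(xl, f"{ini}{fin}_LINE", None)
            if macro is None:
                continue
            try:
                e = xl.LineEnergy(Z, macro)
                cs = xl.CS_FluorLine_Kissel(Z, macro, E_REF)
            except Exception:
                continue
            if e <= 0 or cs <= 0:
                continue
            rows.append([ini + fin, e, cs, edge])
    m = max(r[2] for r in rows)
    for r in rows:
        r[2] = r[2] / m
    return rows

with open('inst/extdata/xray_lines.csv', 'w', newline='') as fh:
    w = csv.writer(fh)
    w.writerow(['element', 'transition', 'energy_keV', 'rel_intensity',
                'edge_keV', 'series'])
    for table, series in ((K_ELEMENTS, 'K'), (L_ELEMENTS, 'L')):
        for Z in sorted(table):
            sym = table[Z]
            for tr, e, ri, edge in sorted(series_lines(Z, series),
                                          key=lambda r: -r[2]):
                w.writerow([sym, tr, f"{e:.4f}", f"{ri:.6g}",
                            f"{edge:.4f}", series])
print("written inst/extdata/xray_lines.csv")
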