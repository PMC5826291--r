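# Built-in FG-domain constructs (printed purification constructs: 33-residue
# His-tag/TEV leader, FG or SG domain, C-terminal cysteine anchor).
.nsp1_residues <- paste0(
  "MSKHHHHSGHHHTGHHHHSGSHHHTGENLYFQGSNFNTPQQNKTPFSFGTANNNSNTTNQ",
  "NSSTGAGAFGTGQSTFGFNNSAPNNTNNANSSITPAFGSNNTGNTAFGNSNPTSNVFGSN",
  "NSTTNTFGSNSAGTSLFGSSSAQQTKSNGTAGGNTFGSSSLFNNSTNSNTTKPAFGGLNF",
  "GGGNNTTPSSTGNANTSNNLFGATANANKPAFSFGATTNDDKKTEPDKPAFSFNSSVGNK",
  "TDAQAPTTGFSFGSQLGGNKTVNEAAKPSLSFGSGSAGANPAGASQPEPTTNEPAKPALS",
  "FGTATSDNKTTNTTPSFSFGAKSDENKAGATSKPAFSFGAKPEEKKDDNSSKPAFSFGAK",
  "SNEDKQDGTAKPAFSFGAKPAEKNNNETSKPAFSFGAKSDEKKDGDASKPAFSFGAKPDE",
  "NKASATSKPAFSFGAKPEEKKDDNSSKPAFSFGAKSNEDKQDGTAKPAFSFGAKPAEKNN",
  "NETSKPAFSFGAKSDEKKDGDASKPAFSFGAKSDEKKDSDSSKPAFSFGTKSNEKKDSGS",
  "SKPAFSFGAKPDEKKNDEVSKPAFSFGAKANEKKESDESKSAFSFGSKPTGKEEGDGAKA",
  "AISFGAKPEEQKSSDTSKPAFTFGAQKDNEKKTETSC"
)

.nsp1s_residues <- paste0(
  "MSKHHHHSGHHHTGHHHHSGSHHHTGENLYFQGSNSNTPQQNKTPSSSGTANNNSNTTNQ",
  "NSSTGAGASGTGQSTSGSNNSAPNNTNNANSSSTPASGSNNTGNTASGNSNPTSNSSGSN",
  "NSTTNTSGSNSAGTSSSGSSSAQQTKSNGTAGGNTSGSSSSSNNSTNSNTTKPASGGSNS",
  "GGGNNTTPSSTGNANTSNNSSGATANANKPASSSGATTNDDKKTEPDKPASSSNSSSGNK",
  "TDAQAPTTGSSSGSQSGGNKTSNEAAKPSSSSGSGSAGANPAGASQPEPTTNEPAKPASS",
  "SGTATSDNKTTNTTPSSSSGAKSDENKAGATSKPASSSGAKPEEKKDDNSSKPASSSGAK",
  "SNEDKQDGTAKPASSSGAKPAEKNNNETSKPASSSGAKSDEKKDGDASKPASSSGAKPDE",
  "NKASATSKPASSSGAKPEEKKDDNSSKPASSSGAKSNEDKQDGTAKPASSSGAKPAEKNN",
  "NETSKPASSSGAKSDEKKDGDASKPASSSGAKSDEKKDSDSSKPASSSGTKSNEKKDSGS",
  "SKPASSSGAKPDEKKNDESSKPASSSGAKANEKKESDESKSASSSGSKPTGKEEGDGAKA",
  "ASSSGAKPEEQKSSDTSKPASTSGAQKDNEKKTESTSC"
)
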