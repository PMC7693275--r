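from	to
ä	ae
ö	oe
ü	ue
Ä	Ae
Ö	Oe
Ü	Ue
ß	ss
æ	ae
Æ	Ae
œ	oe
Œ	Oe
ø	o
Ø	O
å	a
Å	A
á	a
à	a
â	a
ã	a
Á	A
À	A
Â	A
Ã	A
é	e
è	e
ê	e
ë	e
É	E
È	E
Ê	E
Ë	E
í	i
ì	i
î	i
ï	i
Í	I
Ì	I
Î	I
Ï	I
ó	o
ò	o
ô	o
õ	o
Ó	O
Ò	O
Ô	O
Õ	O
ú	u
ù	u
û	u
Ú	U
Ù	U
Û	U
ý	y
ÿ	y
Ý	Y
ñ	n
Ñ	N
ç	c
Ç	C
š	s
Š	S
ž	z
Ž	Z
ć	c
č	c
Č	C
ł	l
Ł	L
ń	n
ř	r
ś	s
ő	o
ű	u
đ	d
Đ	D
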