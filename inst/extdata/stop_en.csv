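word,language,source
a,en,common
about,en,common
after,en,common
against,en,common
all,en,common
also,en,common
am,en,common
an,en,common
and,en,common
any,en,common
are,en,common
as,en,common
at,en,common
be,en,common
because,en,common
been,en,common
before,en,common
being,en,common
best,en,custom
between,en,common
both,en,common
but,en,common
by,en,common
can,en,common
cannot,en,common
come,en,common
completely,en,custom
correctly,en,custom
could,en,common
did,en,common
do,en,common
does,en,common
doing,en,common
down,en,common
during,en,common
each,en,common
early,en,custom
few,en,common
for,en,common
free,en,custom
from,en,common
get,en,common
give,en,common
go,en,common
good,en,custom
had,en,common
has,en,common
have,en,common
having,en,common
he,en,common
her,en,common
here,en,common
hers,en,common
him,en,common
his,en,common
how,en,common
i,en,common
if,en,common
in,en,common
into,en,common
is,en,common
it,en,common
its,en,common
just,en,common
know,en,custom
late,en,custom
like,en,common
long,en,common
make,en,common
many,en,common
me,en,common
mild,en,custom
more,en,common
most,en,common
much,en,common
my,en,common
need,en,custom
no,en,common
not,en,common
now,en,common
of,en,common
off,en,common
on,en,common
once,en,common
one,en,common
only,en,common
or,en,common
other,en,common
our,en,common
out,en,common
over,en,common
own,en,common
please,en,custom
raises,en,custom
run,en,custom
same,en,common
she,en,common
should,en,common
so,en,common
some,en,common
soon,en,custom
such,en,common
suits,en,custom
take,en,common
taking,en,common
tell,en,custom
than,en,common
that,en,common
the,en,common
their,en,common
them,en,common
then,en,common
there,en,common
these,en,common
they,en,common
this,en,common
those,en,common
through,en,common
time,en,common
to,en,common
too,en,common
try,en,custom
under,en,common
until,en,common
up,en,common
us,en,common
use,en,custom
used,en,custom
using,en,custom
very,en,common
want,en,custom
was,en,common
we,en,common
well,en,common
were,en,common
what,en,common
when,en,common
where,en,common
which,en,common
while,en,common
who,en,common
whom,en,common
why,en,common
will,en,common
with,en,common
within,en,common
worried,en,custom
would,en,common
you,en,common
your,en,common
yours,en,common
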