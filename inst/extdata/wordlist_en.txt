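a
abdominal
about
acting
adult
advice
affect
afford
afraid
after
against
age
am
an
and
any
anytime
are
ask
asking
at
attention
available
balanced
be
benefits
best
bleeding
body
both
boyfriend
breast
breastfeeding
breasts
burst
calendar
can
cancer
causes
cervical
cervix
changing
check
checkups
chemist
children
choice
clinic
coil
common
completely
conceive
concerns
condom
condoms
confidential
consider
contacting
contraception
correctly
cost
counselling
count
county
cycle
days
delay
details
detect
detected
diet
discharge
dizziness
do
does
drawbacks
drink
during
early
effective
effects
emergency
enlargement
every
families
family
feel
fertility
few
first
follow
for
free
from
get
girlfriend
good
happy
has
have
headache
health
healthy
help
her
here
hiv
hormonal
hospitals
how
husband
i
if
implant
in
infection
information
injection
irregular
is
it
kept
kiss
kissing
know
ksh
lasts
late
let
long
low
lower
many
marriage
me
medicine
men
menses
menstruation
method
methods
mild
missed
missing
month
more
most
mother
much
my
nausea
nearest
need
needs
normal
not
nurse
of
one
or
oral
other
our
ovulation
pain
painful
partner
pass
people
performance
period
periods
pill
pills
planning
please
plenty
positive
pregnancy
pregnant
prevent
prevention
private
problems
prostate
protect
protection
question
questions
raises
reduce
regular
relationship
remove
requested
rest
risk
run
safe
safety
same
screen
screening
service
services
sex
share
should
side
signs
single
soon
space
spacing
sperm
spotting
stress
suits
supports
swollen
symptoms
taking
talk
tell
test
than
thank
that
the
their
three
time
to
transmit
transmitted
trusted
try
two
unprotected
unwell
up
urination
us
use
used
vary
vasectomy
virus
visit
vomiting
want
water
we
weight
what
when
where
which
while
wife
will
with
withdrawal
within
women
work
works
worried
worries
worry
years
you
young
your
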